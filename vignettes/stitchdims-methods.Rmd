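---
title: "Methods: spectral-stitching DIMS processing in stitchdims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-stitching DIMS processing in stitchdims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, parameter choices and numerical
decisions behind `stitchdims`, in the spirit of a statistical methods
section: what each stage assumes, which knobs matter, and what the
validation on synthetic data does and does not demonstrate.

## The acquisition model

A spectral-stitching nESI-DIMS run covers the m/z range with
overlapping SIM windows to extend dynamic range; each window is scanned
several times within the single infusion of a sample ("internal scan
replication"). A real peak should therefore recur across the scans of
its window, while electronic noise and spray instabilities should not.
The processing chain turns this structure into a filter cascade:
within-window alignment → replicate filter → window stitching →
cross-sample alignment → blank filter → presence filter.

`stitchdims` makes the following structural assumptions, all standard
for centroided chip-based nESI acquisitions of polar metabolites:
singly charged ions, no chromatographic dimension, no isotopologue or
multimer handling, and peak identity carried entirely by m/z proximity.

## The synthetic-acquisition generator

No instrument data ship with the package, so every stage is validated
against a simulator whose ground truth is known exactly. Its defaults
are chosen to emulate a plausible 96-well plate experiment:

* **Windows**: six 100-Da windows spanning m/z 50–600 with 10 Da
  overlap. Real window schemes are instrument-method specific and not
  standardised; the ranges are fully configurable and all tests state
  theirs explicitly.
* **Internal scan replicates**: 4 per window, matching the 3-of-4
  replicate rule.
* **Technical noise**: multiplicative lognormal with σ² = ln(1 + cv²),
  so that the realised coefficient of variation equals `technical_cv`
  exactly — the natural choice when downstream quality metrics are
  RSD-based. The default cv of 0.10 reproduces pooled-QC median RSDs
  around 9–10%, the regime a well-behaved DIMS assay operates in. One
  noise draw is made per well × ion and **shared across the internal
  scan replicates** of that infusion: the scans of one infusion observe
  the same electrospray at essentially the same moment, whereas
  well-to-well (injection-to-injection) variation is what QC RSDs
  measure. Had noise been drawn per scan, the replicate-mean step would
  deterministically shrink feature CVs by √4 and the QC-filter
  behaviour would no longer reflect the configured cv.
* **Dropout**: each true peak is omitted from any one scan
  independently with probability `peak_dropout_prob` (default 0.05).
  Dropout is missingness, not zero intensity, and stays distinguishable
  from zero throughout the pipeline.
* **m/z jitter**: uniform within ±`mz_jitter_ppm` (default 1 ppm),
  drawn per peak per scan, stressing the ppm-clustering alignment.
* **Drift**: a global sensitivity factor applied to all peaks of an
  injection; `drift_magnitude` is the *total* fractional change from
  the first to the last injection (0.3 = +30% across the run), linear
  or exponential in injection order.
* **Plates**: 8 × 12 wells; edge wells are those in the first/last row
  or column. Wells carry class (sample/QC/blank/empty), exposure group,
  time point, an optional per-well dilution factor and an optional
  per-well technical-cv override (used to emulate edge-versus-centre
  variability differences).
* **Blanks** receive contaminants at full intensity by default — the
  worst case for the blank filter; an attenuation factor provides
  softer cases.
* **Metabolite libraries**: masses drawn uniformly with a minimum
  pairwise separation of 20 ppm between all emitted adduct m/z values.
  This is a deliberate generator property: ground truth must be
  unambiguous for exact-recovery oracles. Real spectra contain
  near-isobaric overlaps that no ppm-clustering method can split; the
  simulator does not emulate them, so passing the recovery oracles says
  nothing about overlap resolution.

Other real-data features the simulator does **not** emulate: profile
peak shapes, intensity-dependent mass error, ion suppression and
cross-well carryover, correlated (compound-wise) biological variation,
heteroscedastic additive detector noise, and charge states above one.
Conclusions from the synthetic validation transfer to real data only to
the extent these effects are secondary to the multiplicative-noise,
dropout and drift structure that is emulated.

## Alignment and stitching

**ppm metric.** All clustering operates on u = 10⁶·ln(m/z), where
differences are symmetric ppm distances (to first order in the
tolerance). This avoids the asymmetry of defining ppm relative to one
of the two peaks.

**Clustering.** Peaks are sorted and split wherever the gap between
neighbours exceeds the tolerance — exactly single-linkage clustering
with a cut, computed in O(n log n) and fully deterministic. When one
scan replicate (or, across samples, one sample) contributes two peaks
to a group, the group is split recursively at its largest internal gap.
Consequence of single linkage: a chain of peaks each within tolerance
of its neighbour is one group even if its total diameter exceeds the
tolerance. The within-sample default is 2 ppm, the across-sample
default 3 ppm (cross-sample spread adds calibration differences);
both exceed the simulated 1 ppm jitter with headroom and sit in the
range routinely used for Orbitrap data.

**Group intensity** is the arithmetic mean over the replicates in which
the peak occurs (not over all n): dropout is modelled as missingness.
Group m/z is the intensity-weighted mean.

**Replicate filter**: keep groups present in ≥ 3 of 4 scans (both
counts configurable; `≥` semantics, so a peak exactly at the threshold
survives). Under independent dropout with probability p the survival
probability is (1−p)⁴ + 4p(1−p)³, which the test suite verifies
empirically within Monte-Carlo error on 30,000 simulated peak trials
per dropout rate.

**Stitching.** Each window keeps only an effective range: at the
default `midpoint` mode every overlap is split at its midpoint; in
`edge_margin` mode a fixed margin (default 2 Da) is discarded from each
shared window edge, mimicking edge-effect trimming in SIM acquisitions.
A jittered peak straddling a trim boundary can survive in both windows;
a final ppm-proximity pass deduplicates, keeping the copy from the
window whose centre is nearer the peak (ties to the lower window
index) and counting removals.

**Blank filter.** A feature is removed when it occurs in at least
`blank_min_fraction` (default all) of blank wells and its mean
intensity over non-blank samples is below `blank_fold` (default 10)
times its mean over the blanks where present. A feature absent from
the samples but present in blanks has sample mean 0 and is removed.
Calling the filter on a matrix without blanks is an error rather than a
silent no-op.

**Presence filter.** Default: ≥ 80% non-missing over all samples;
a per-class mode requires the threshold within every class.

## Normalisation and quality control

**PQN.** The reference spectrum is the per-feature median over pooled
QC samples when present — the pooled QC is by construction the average
biological material, making it the natural dilution reference — else
the median over all samples. Each sample is divided by the median of
its per-feature quotients against the reference; quotients use only
features observed in both. Samples sharing fewer than 10 features with
the reference warn. Missing values stay missing.

**RSD** uses the sample (n−1) standard deviation — class sizes in
plate-qualification designs are small (8–10) — and returns an explicit
undefined marker (`NA`, never 0) for fewer than two values or a
non-positive mean. Filters treat undefined as failing. One consequence,
verified in the tests: pooling two identical copies of a group rescales
every sd by √(2(n−1)/(2n−1)), so merged-group mRSDs are not exactly the
per-group mRSDs.

**QC-RSD filter** removes features whose QC RSD exceeds 30% (default)
or is undefined. A distributional note that matters when interpreting
it: with n = 8 QCs, the sample RSD is itself noisy. At a true CV of
10%, essentially every feature passes the 30% threshold; at a true CV
of 50%, the Monte-Carlo sampling distribution of the n = 8 RSD puts
≈ 11% of features *below* 30%, so the filter removes ≈ 89–91% of
genuinely unstable features, not ≈ 100%. The test suite checks the
filter against this sampling distribution rather than against an
idealised complete-removal expectation.

**Drift correction** fits, per feature, a degree-1 loess (span 0.75,
direct surface; smoothing-spline alternative) through the QC
intensities versus injection order, divides every sample by the trend
at its own injection order and rescales to the feature's QC median.
Features with fewer than 4 non-missing QC values pass through
uncorrected and are counted. At least 4 QC injections spread over the
run are required. The corrector is QC-anchored and global per
injection, matching the simulator's drift model; it cannot correct
feature-specific drift. Because the trend interpolates part of the QC
noise, corrected QC mRSDs can come out marginally *below* the
drift-free level; the validation asserts agreement within 2 percentage
points in both directions.

**Order of operations** in `run_study()` is fixed and logged: presence
filter → PQN → drift correction → QC-RSD filter. Blank filtering
happens earlier, at matrix construction, so that normalisation never
sees contaminant features.

## Statistics

**Imputation** (PCA only): k-nearest-neighbour over features (features
vastly outnumber samples in DIMS matrices, giving stable
neighbourhoods), Euclidean distance on jointly observed samples
normalised per shared sample, distance-weighted mean of the k = 5
nearest features observed in the target sample; exact-duplicate
neighbours (distance 0) take full weight. Hypothesis tests always run
on non-imputed values.

**glog**: g(x) = ln((x + √(x² + λ))/2); λ = 0 recovers ln(x). λ is
estimated as the median technical variance of the lowest-intensity
decile of features (from QC replicates when available), i.e. an
additive-noise-floor estimate. Estimating λ from all features would be
dominated by high-intensity multiplicative variance and linearise the
low-intensity range, defeating the stabilisation.

**PCA** is the SVD of the mean-centred matrix; component signs follow a
fixed convention (largest-magnitude loading positive) so scores are
platform-reproducible. **Outlier flagging** uses median/MAD-robust
z-scores on the first two PCs and a χ²₂ 97.5% boundary; samples are
flagged, never auto-removed — rerunning without them is an explicit
pipeline option. The robust rule is a documented stand-in for whatever
manual inspection a study would apply; it flags ≈ 2.5–4% of
homogeneous Gaussian scores.

**ANOVA** is a vectorised per-feature one-way decomposition over
non-missing values; groups entirely missing for a feature are dropped
(the feature is tested if ≥ 2 groups remain, else skipped and
counted); features with zero total variance get p = 1. Adjustment is
Benjamini–Hochberg across features (method configurable); the
significant set is adjusted p ≤ α = 0.05. Agreement with `aov()` is
asserted to 10⁻¹⁰ on matrices with missingness.

**Tukey–Kramer**: pairwise studentised-range tests with the unequal-n
standard error √(MSE/2·(1/nᵢ+1/nⱼ)), reducing to classical Tukey HSD
for balanced groups; p-values from the studentised-range distribution
with N−k error degrees of freedom. The independent oracle in the tests
is `stats::TukeyHSD`.

**Time courses**: between each pair of consecutive time points the
two-group test is run per feature, FDR-corrected, and the count of
significant features divided by the interval length in hours — making
unevenly spaced designs (1, 2, 6, 24, 48 h) comparable. The
all-time-points summary is the strict intersection of the per-time
significant sets.

## Annotation

Adduct mass shifts are computed from a bundled monoisotopic atomic-mass
table, including the electron mass (≈ 0.00055 Da, near the 5 ppm floor
for small molecules but free to get right). "Hac" is acetic acid,
consistent with ammonium-acetate negative-mode buffers. Matching uses a
sorted interval search over all (compound, adduct) theoretical m/z
values — the tolerance window |10⁶(obs−theo)/theo| ≤ t is inverted to
theo ∈ [obs/(1+t·10⁻⁶), obs/(1−t·10⁻⁶)] — and is asserted equal to the
all-pairs scan. All matches within tolerance are reported, ranked per
feature by |ppm error|; annotation is putative and deliberately
non-unique, and intensities play no role. Database curation (e.g.
removing exogenous compounds) is the responsibility of the supplied
table.

## Problem sizes and determinism

The validation suite uses plates of 8–96 wells, libraries of 80–500
ions, 30,000 peak trials per dropout rate for the survival law, 100
seeds for PQN dilution recovery and 200 null replicates for FDR
control — sizes at which every Monte-Carlo band in the tests is
derived from the corresponding sampling distribution, and the whole
suite plus the acceptance script run in well under a minute each on a
single core. All randomness flows through explicit integer seeds; the
simulator restores the caller's RNG state, and rerunning any pipeline
with the same seed produces byte-identical output files.

## Known limitations

* Single-linkage chaining can merge peaks whose total spread exceeds
  the ppm cut; with the 20 ppm generator separation this never occurs
  in validation, but dense real spectra may need the tolerance lowered.
* The drift corrector assumes a smooth global trend sampled by QCs;
  step changes between QCs, or feature-specific drift, pass through.
* mzML ingestion requires centroided spectra and an explicit window
  map; instrument scan-event naming is too heterogeneous to guess.
* The bundled mzML writer emits the minimal subset of the standard
  needed to exercise ingestion (uncompressed 64-bit arrays, MS1
  centroid spectra with scan-window limits); it is a synthetic-data
  export, not a converter.
* No isotope patterns, multimers, multiple charging or MS/MS evidence
  anywhere in the pipeline; annotation is accurate-mass-only and its
  false-positive behaviour on real databases is correspondingly
  untested here.
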