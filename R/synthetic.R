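# Synthetic spectral-stitching DIMS acquisitions with known ground truth.
#
# The simulator emulates the acquisition structure of a chip-based nESI
# direct-infusion run on 96-well plates: overlapping SIM windows, each
# acquired as several internal scan replicates within a single infusion,
# pooled-QC and extraction-blank wells, injection-order sensitivity drift,
# multiplicative technical noise, per-scan peak dropout and m/z jitter.

#' Default overlapping SIM window ranges
#'
#' Six 100-Da windows spanning m/z 50-600 with 10 Da overlap between
#' consecutive windows. Instrument window schemes vary; these defaults are
#' a documented assumption and fully configurable.
#'
#' @return matrix with columns `mz_low`, `mz_high`.
#' @export
default_windows <- function() {
  lo <- seq(50, 550, by = 90)[1:6]
  cbind(mz_low = lo, mz_high = lo + 100)
}

#' Acquisition configuration for the simulator
#'
#' @param window_ranges two-column matrix (`mz_low`, `mz_high`) of SIM
#'   windows; consecutive windows must overlap.
#' @param n_internal_replicates scans acquired per window per infusion
#'   (default 4).
#' @param technical_cv coefficient of variation of the multiplicative
#'   lognormal technical noise, drawn once per well x ion and shared by
#'   the internal scan replicates of that infusion.
#' @param peak_dropout_prob probability that a true peak is missing from
#'   any one scan replicate (independent per window x scan).
#' @param mz_jitter_ppm half-width of the uniform per-peak-per-scan m/z
#'   perturbation, in ppm.
#' @param drift_model `"none"`, `"linear"` or `"exponential"` global
#'   sensitivity drift over the injection sequence.
#' @param drift_magnitude total fractional intensity change from the first
#'   to the last injection (0.3 = +30% across the run).
#' @param noise_peaks_per_window spurious low-SNR peaks added per window
#'   per scan (default 0).
#' @param noise_snr_range SNR range for spurious peaks (below any sensible
#'   SNR threshold by default).
#' @param signal_snr SNR tagged onto true peaks.
#' @param blank_attenuation contaminant intensity in blank wells relative
#'   to other wells (1 = full intensity, the worst case for blank
#'   filtering).
#' @param seed integer seed; identical configurations give byte-identical
#'   simulations.
#' @return object of class `acquisition_config`.
#' @export
acquisition_config <- function(window_ranges = default_windows(),
                               n_internal_replicates = 4L,
                               technical_cv = 0.10,
                               peak_dropout_prob = 0.05,
                               mz_jitter_ppm = 1.0,
                               drift_model = c("none", "linear", "exponential"),
                               drift_magnitude = 0,
                               noise_peaks_per_window = 0L,
                               noise_snr_range = c(0.5, 2.9),
                               signal_snr = 50,
                               blank_attenuation = 1,
                               seed = 1L) {
  drift_model <- match.arg(drift_model)
  window_ranges <- as.matrix(window_ranges)
  stopifnot(ncol(window_ranges) == 2, nrow(window_ranges) >= 1,
            all(window_ranges[, 2] > window_ranges[, 1]),
            n_internal_replicates >= 1,
            technical_cv >= 0, mz_jitter_ppm >= 0,
            peak_dropout_prob >= 0, peak_dropout_prob <= 1,
            blank_attenuation >= 0, blank_attenuation <= 1,
            signal_snr > 0)
  o <- order(window_ranges[, 1])
  window_ranges <- window_ranges[o, , drop = FALSE]
  if (nrow(window_ranges) > 1) {
    nxt_lo <- window_ranges[-1, 1]
    prv_hi <- window_ranges[-nrow(window_ranges), 2]
    if (any(nxt_lo >= prv_hi)) {
      stop("consecutive SIM windows must overlap (next mz_low < previous mz_high)",
           call. = FALSE)
    }
  }
  colnames(window_ranges) <- c("mz_low", "mz_high")
  structure(list(window_ranges = window_ranges,
                 n_internal_replicates = as.integer(n_internal_replicates),
                 technical_cv = technical_cv,
                 peak_dropout_prob = peak_dropout_prob,
                 mz_jitter_ppm = mz_jitter_ppm,
                 drift_model = drift_model,
                 drift_magnitude = drift_magnitude,
                 noise_peaks_per_window = as.integer(noise_peaks_per_window),
                 noise_snr_range = noise_snr_range,
                 signal_snr = signal_snr,
                 blank_attenuation = blank_attenuation,
                 seed = as.integer(seed)),
            class = "acquisition_config")
}

#' Generate a ground-truth metabolite library
#'
#' Draws neutral monoisotopic masses uniformly over `mz_range` (shifted so
#' the emitted adduct m/z values fall in range) with lognormal base
#' intensities. All emitted adduct m/z values are kept at least
#' `min_separation_ppm` apart so that ground-truth features are
#' unambiguous under ppm alignment.
#'
#' @param n_metabolites number of endogenous metabolites.
#' @param n_contaminants number of blank-borne contaminants (present in
#'   every well including blanks).
#' @param mz_range target m/z range for emitted ions.
#' @param adducts character vector of adduct names each metabolite emits
#'   (default `"[M-H]-"`; a vector emits every listed adduct per
#'   metabolite).
#' @param intensity_meanlog,intensity_sdlog lognormal parameters of base
#'   intensities (ion-count scale).
#' @param min_separation_ppm minimum pairwise separation between emitted
#'   ions.
#' @param seed integer seed.
#' @return data.frame with columns `id`, `monoisotopic_mass`,
#'   `base_intensity`, `adducts` (`;`-separated), `is_contaminant`.
#' @export
metabolite_library <- function(n_metabolites = 200L, n_contaminants = 0L,
                               mz_range = c(70, 580), adducts = "[M-H]-",
                               intensity_meanlog = log(1e5),
                               intensity_sdlog = 0.8,
                               min_separation_ppm = 20, seed = 1L) {
  stopifnot(n_metabolites >= 1, n_contaminants >= 0)
  rules <- adduct_rules()
  idx <- match(adducts, rules$name)
  if (anyNA(idx)) stop("unknown adduct name(s)", call. = FALSE)
  shifts <- rules$mass_shift[idx]
  n <- n_metabolites + n_contaminants
  .with_seed(seed, {
    mass_lo <- mz_range[1] - min(shifts)
    mass_hi <- mz_range[2] - max(shifts)
    masses <- numeric(0)
    tries <- 0L
    while (length(masses) < n && tries < 200L) {
      cand <- sort(c(masses, runif(n - length(masses), mass_lo, mass_hi)))
      # enforce separation between every pair of emitted ions
      ions <- sort(as.vector(outer(cand, shifts, "+")))
      ok_ion <- c(TRUE, diff(ions) / ions[-length(ions)] * 1e6 >= min_separation_ppm)
      bad_ion <- ions[!ok_ion]
      bad_mass <- unique(unlist(lapply(shifts, function(s) {
        cand[vapply(cand, function(m) any(abs(m + s - bad_ion) < 1e-9), logical(1))]
      })))
      masses <- setdiff(cand, bad_mass)
      tries <- tries + 1L
    }
    if (length(masses) < n) {
      stop("could not place ", n, " metabolites at ", min_separation_ppm,
           " ppm separation in the given m/z range", call. = FALSE)
    }
    masses <- sample(masses, n)  # decouple id order from mass order
    data.frame(
      id = sprintf("MET%04d", seq_len(n)),
      monoisotopic_mass = masses,
      base_intensity = rlnorm(n, intensity_meanlog, intensity_sdlog),
      adducts = paste(adducts, collapse = ";"),
      is_contaminant = rep(c(FALSE, TRUE), c(n_metabolites, n_contaminants)),
      stringsAsFactors = FALSE
    )
  })
}

#' Plant multiplicative class effects on selected metabolites
#'
#' @param metabolites a metabolite library (see [metabolite_library()]).
#' @param ids metabolite ids to perturb.
#' @param exposure exposure-group label the effect applies to.
#' @param time_h time point (hours) the effect applies to; `NA` = all.
#' @param fold multiplicative fold change (> 0).
#' @return data.frame of effects, rbind-able across calls.
#' @export
plant_effects <- function(metabolites, ids, exposure, time_h = NA_real_, fold) {
  stopifnot(all(ids %in% metabolites$id), all(fold > 0))
  expand <- expand.grid(metabolite_id = ids, exposure = exposure,
                        time_h = time_h, stringsAsFactors = FALSE)
  expand$fold <- fold
  expand
}

#' Build a 96-well plate layout
#'
#' Wells are filled row-major from A1 on an 8 x 12 grid. Edge wells are
#' those in the first/last row or column; all others are centre wells.
#'
#' @param n_samples,n_qc,n_blank well counts by class (total <= 96).
#' @param plate_id plate identifier.
#' @param exposure exposure-group labels recycled across sample wells.
#' @param time_h time points (hours) recycled across sample wells (crossed
#'   with `exposure`: the i-th sample well gets
#'   `exposure[(i-1) %% length + 1]` etc. after `expand.grid` recycling).
#' @param dilution per-well global dilution factor (recycled over sample
#'   wells; QC/blank wells get 1).
#' @param technical_cv optional per-well override of the configuration's
#'   technical CV (recycled over sample wells; `NA` = use config).
#' @return data.frame layout with columns `plate_id`, `well`, `row`,
#'   `column`, `class`, `exposure`, `time_h`, `dilution`, `technical_cv`,
#'   `position_class`, `sample_id`.
#' @export
plate_layout <- function(n_samples, n_qc = 0L, n_blank = 0L,
                         plate_id = "P1", exposure = "none",
                         time_h = 0, dilution = 1,
                         technical_cv = NA_real_) {
  n <- n_samples + n_qc + n_blank
  if (n > 96) stop("at most 96 wells per plate", call. = FALSE)
  stopifnot(n_samples >= 0, n_qc >= 0, n_blank >= 0, n >= 1)
  grid <- expand.grid(column = 1:12, row = LETTERS[1:8],
                      stringsAsFactors = FALSE)[seq_len(n), c("row", "column")]
  cls <- rep(c("sample", "QC", "blank"), c(n_samples, n_qc, n_blank))
  design <- expand.grid(exposure = exposure, time_h = time_h,
                        stringsAsFactors = FALSE)
  di <- rep_len(seq_len(nrow(design)), max(n_samples, 1L))
  layout <- data.frame(
    plate_id = plate_id,
    well = sprintf("%s%02d", grid$row, grid$column),
    row = grid$row, column = grid$column, class = cls,
    exposure = NA_character_, time_h = NA_real_,
    dilution = 1, technical_cv = NA_real_,
    stringsAsFactors = FALSE
  )
  if (n_samples > 0) {
    si <- which(cls == "sample")
    layout$exposure[si] <- design$exposure[di]
    layout$time_h[si] <- design$time_h[di]
    layout$dilution[si] <- rep_len(dilution, n_samples)
    layout$technical_cv[si] <- rep_len(technical_cv, n_samples)
  }
  as_plate_layout(layout)
}

#' Validate a layout data.frame and derive positional metadata
#'
#' @param layout data.frame with at least `plate_id`, `well`, `row`,
#'   `column`, `class`.
#' @return validated layout with `position_class` and `sample_id` added.
#' @export
as_plate_layout <- function(layout) {
  need <- c("plate_id", "well", "row", "column", "class")
  if (!all(need %in% names(layout))) {
    stop("layout must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(layout) < 1) stop("layout is empty", call. = FALSE)
  if (anyDuplicated(layout[c("plate_id", "well")])) {
    stop("duplicate wells in layout", call. = FALSE)
  }
  if (!all(layout$class %in% c("sample", "QC", "blank", "empty"))) {
    stop("well class must be sample, QC, blank or empty", call. = FALSE)
  }
  if (!all(layout$row %in% LETTERS[1:8]) || !all(layout$column %in% 1:12)) {
    stop("rows must be A-H and columns 1-12", call. = FALSE)
  }
  for (col in c("exposure", "time_h")) if (!col %in% names(layout)) layout[[col]] <- NA
  if (!"dilution" %in% names(layout)) layout$dilution <- 1
  if (!"technical_cv" %in% names(layout)) layout$technical_cv <- NA_real_
  layout$position_class <- ifelse(
    layout$row %in% c("A", "H") | layout$column %in% c(1, 12), "edge", "centre")
  layout$sample_id <- paste(layout$plate_id, layout$well, sep = "_")
  layout
}

#' Block-randomised acquisition order with interleaved QCs
#'
#' Non-QC wells are shuffled within blocks (per plate or per class); QC
#' wells are then inserted at a fixed period through the injection
#' sequence, mirroring common pooled-QC scheduling.
#'
#' @param layout a plate layout (see [as_plate_layout()]).
#' @param seed integer seed; the same seed reproduces the same order.
#' @param block_by `"plate"` or `"class"`.
#' @param qc_period insert a QC every `qc_period` injections starting at
#'   position 1 (`NULL` = shuffle QCs within their block instead).
#' @return the layout with an `injection_order` column (1-based),
#'   excluding `empty` wells from the sequence.
#' @export
blocked_acquisition_order <- function(layout, seed = 1L,
                                      block_by = c("plate", "class"),
                                      qc_period = NULL) {
  block_by <- match.arg(block_by)
  layout <- as_plate_layout(layout)
  active <- which(layout$class != "empty")
  .with_seed(seed, {
    if (is.null(qc_period)) {
      key <- if (block_by == "plate") layout$plate_id[active] else
        paste(layout$plate_id[active], layout$class[active])
      ord <- unlist(lapply(split(active, key), sample), use.names = FALSE)
    } else {
      qcs <- active[layout$class[active] == "QC"]
      rest <- active[layout$class[active] != "QC"]
      key <- if (block_by == "plate") layout$plate_id[rest] else
        paste(layout$plate_id[rest], layout$class[rest])
      rest <- unlist(lapply(split(rest, key), sample), use.names = FALSE)
      qcs <- sample(qcs)
      ord <- integer(0)
      while (length(qcs) || length(rest)) {
        if (length(qcs) && (length(ord) %% qc_period == 0 || !length(rest))) {
          ord <- c(ord, qcs[1]); qcs <- qcs[-1]
        } else {
          take <- min(qc_period - 1L, length(rest))
          if (!length(qcs)) take <- length(rest)
          ord <- c(ord, rest[seq_len(take)]); rest <- rest[-seq_len(take)]
        }
      }
    }
    layout$injection_order <- NA_integer_
    layout$injection_order[ord] <- seq_along(ord)
    layout
  })
}

# evaluate the global drift factor at an injection position
.drift_factor <- function(order, n_total, model, magnitude) {
  frac <- if (n_total > 1) (order - 1) / (n_total - 1) else 0
  switch(model,
         none = rep(1, length(order)),
         linear = 1 + magnitude * frac,
         exponential = exp(log1p(magnitude) * frac))
}

# run code with a private, restored RNG stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate a plate of spectral-stitching DIMS acquisitions
#'
#' Every non-empty well is "infused" once: each SIM window is scanned
#' `n_internal_replicates` times, each true ion lands in every window that
#' covers its m/z (overlap regions emit it twice, exercising the
#' stitcher), intensities carry class effects, dilution, injection-order
#' drift and shared multiplicative technical noise, and each scan
#' independently drops peaks and jitters m/z. Blank wells contain only
#' contaminants.
#'
#' @param layout plate layout; if it lacks `injection_order` a blocked
#'   order is derived with the configuration seed.
#' @param metabolites metabolite library (see [metabolite_library()]).
#' @param config an [acquisition_config()].
#' @param effects optional planted effect table (see [plant_effects()]).
#' @return list of class `dims_simulation` with elements `scans` (long
#'   peak table: `sample_id`, `window_index`, `replicate_index`, `mz`,
#'   `intensity`, `snr`), `truth` (per well x metabolite x adduct:
#'   `true_mz`, `true_intensity`, `in_window`), `layout`, and `unplaced`
#'   (ions falling outside every window; also raised as a warning).
#' @export
simulate_plate <- function(layout, metabolites, config, effects = NULL) {
  stopifnot(inherits(config, "acquisition_config"), nrow(metabolites) >= 1)
  layout <- as_plate_layout(layout)
  if (!"injection_order" %in% names(layout)) {
    layout <- blocked_acquisition_order(layout, seed = config$seed)
  }
  wins <- config$window_ranges
  rules <- adduct_rules()

  # expand metabolite x adduct ions once
  adds <- strsplit(metabolites$adducts, ";", fixed = TRUE)
  ions <- data.frame(
    metabolite_id = rep(metabolites$id, lengths(adds)),
    monoisotopic_mass = rep(metabolites$monoisotopic_mass, lengths(adds)),
    base_intensity = rep(metabolites$base_intensity, lengths(adds)),
    is_contaminant = rep(metabolites$is_contaminant, lengths(adds)),
    adduct = unlist(adds), stringsAsFactors = FALSE
  )
  ions$true_mz <- adduct_mz(ions$monoisotopic_mass,
                            rules[match(ions$adduct, rules$name), ])
  in_win <- outer(ions$true_mz, wins[, 1], ">=") & outer(ions$true_mz, wins[, 2], "<=")
  ions$in_window <- rowSums(in_win) > 0
  unplaced <- ions[!ions$in_window,
                   c("metabolite_id", "adduct", "true_mz"), drop = FALSE]
  if (nrow(unplaced) > 0) {
    warning(nrow(unplaced), " ion(s) fall outside every SIM window ",
            "(recorded in $unplaced)", call. = FALSE)
  }

  active <- which(layout$class != "empty")
  n_inj <- max(layout$injection_order, na.rm = TRUE)
  scan_chunks <- vector("list", 0L)
  truth_chunks <- vector("list", length(active))

  .with_seed(config$seed, {
    for (k in seq_along(active)) {
      w <- active[k]
      is_blank <- layout$class[w] == "blank"
      sel <- if (is_blank) which(ions$is_contaminant) else seq_len(nrow(ions))
      if (!length(sel)) {
        truth_chunks[[k]] <- NULL
        next
      }
      ion <- ions[sel, , drop = FALSE]
      fold <- rep(1, nrow(ion))
      if (!is.null(effects) && nrow(effects) && layout$class[w] == "sample") {
        for (j in seq_len(nrow(effects))) {
          hit <- ion$metabolite_id == effects$metabolite_id[j] &
            identical_or_na(effects$exposure[j], layout$exposure[w]) &
            identical_or_na(effects$time_h[j], layout$time_h[w])
          fold[hit] <- fold[hit] * effects$fold[j]
        }
      }
      cv <- layout$technical_cv[w]
      if (is.na(cv)) cv <- config$technical_cv
      noise <- if (cv > 0) {
        s2 <- log(1 + cv^2)
        rlnorm(nrow(ion), -s2 / 2, sqrt(s2))
      } else rep(1, nrow(ion))
      drift <- .drift_factor(layout$injection_order[w], n_inj,
                             config$drift_model, config$drift_magnitude)
      atten <- if (is_blank) config$blank_attenuation else 1
      intensity <- ion$base_intensity * fold * layout$dilution[w] *
        drift * noise * atten
      truth_chunks[[k]] <- data.frame(
        sample_id = layout$sample_id[w], well = layout$well[w],
        plate_id = layout$plate_id[w], class = layout$class[w],
        metabolite_id = ion$metabolite_id, adduct = ion$adduct,
        true_mz = ion$true_mz, true_intensity = intensity,
        in_window = ion$in_window,
        injection_order = layout$injection_order[w],
        stringsAsFactors = FALSE
      )
      for (wi in seq_len(nrow(wins))) {
        hit <- which(ion$true_mz >= wins[wi, 1] & ion$true_mz <= wins[wi, 2])
        for (r in seq_len(config$n_internal_replicates)) {
          keep <- hit
          if (config$peak_dropout_prob > 0 && length(hit)) {
            keep <- hit[runif(length(hit)) >= config$peak_dropout_prob]
          }
          mz <- ion$true_mz[keep]
          if (config$mz_jitter_ppm > 0 && length(keep)) {
            mz <- mz * (1 + runif(length(keep), -config$mz_jitter_ppm,
                                  config$mz_jitter_ppm) * 1e-6)
          }
          chunk <- data.frame(
            sample_id = rep(layout$sample_id[w], length(keep)),
            window_index = rep(wi, length(keep)),
            replicate_index = rep(r, length(keep)),
            mz = mz, intensity = intensity[keep],
            snr = rep(config$signal_snr, length(keep)),
            stringsAsFactors = FALSE
          )
          if (config$noise_peaks_per_window > 0) {
            nn <- config$noise_peaks_per_window
            chunk <- rbind(chunk, data.frame(
              sample_id = rep(layout$sample_id[w], nn),
              window_index = rep(wi, nn), replicate_index = rep(r, nn),
              mz = runif(nn, wins[wi, 1], wins[wi, 2]),
              intensity = rlnorm(nn, log(100), 0.5),
              snr = runif(nn, config$noise_snr_range[1],
                          config$noise_snr_range[2]),
              stringsAsFactors = FALSE
            ))
          }
          if (nrow(chunk)) {
            scan_chunks[[length(scan_chunks) + 1L]] <- chunk[order(chunk$mz), ]
          }
        }
      }
    }
    scans <- do.call(rbind, scan_chunks)
    rownames(scans) <- NULL
    truth <- do.call(rbind, truth_chunks)
    rownames(truth) <- NULL
    structure(list(scans = scans, truth = truth, layout = layout,
                   config = config, unplaced = unplaced),
              class = "dims_simulation")
  })
}

# equality treating NA in the effect spec as a wildcard
identical_or_na <- function(spec, value) {
  is.na(spec) | (!is.na(value) & spec == value)
}

#' @export
print.dims_simulation <- function(x, ...) {
  cat("dims_simulation: ", length(unique(x$scans$sample_id)), " wells, ",
      nrow(x$config$window_ranges), " windows x ",
      x$config$n_internal_replicates, " scan replicates, ",
      nrow(x$scans), " peaks\n", sep = "")
  invisible(x)
}

#' Feature matrix built directly from simulation ground truth
#'
#' Bypasses peak-list processing: one feature per emitted ion
#' (metabolite x adduct), one row per non-empty well, values equal to the
#' realised per-well intensities (noise, effects, dilution and drift
#' included). Useful for exercising normalisation, drift correction and
#' statistics in isolation from the stitching stages.
#'
#' @param sim a `dims_simulation` from [simulate_plate()].
#' @param in_window_only drop ions outside every SIM window
#'   (default TRUE).
#' @return a [feature_matrix()].
#' @export
truth_matrix <- function(sim, in_window_only = TRUE) {
  tr <- sim$truth
  if (in_window_only) tr <- tr[tr$in_window, , drop = FALSE]
  ion <- paste(tr$metabolite_id, tr$adduct)
  ions <- unique(data.frame(ion = ion, mz = tr$true_mz,
                            stringsAsFactors = FALSE))
  ions <- ions[order(ions$mz), , drop = FALSE]
  lay <- sim$layout[sim$layout$class != "empty", , drop = FALSE]
  vals <- matrix(NA_real_, nrow = nrow(lay), ncol = nrow(ions),
                 dimnames = list(lay$sample_id, ions$ion))
  vals[cbind(match(tr$sample_id, lay$sample_id), match(ion, ions$ion))] <-
    tr$true_intensity
  features <- data.frame(feature_id = ions$ion, mz = ions$mz,
                         stringsAsFactors = FALSE)
  feature_matrix(vals, features, lay)
}
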