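test_that("SNR filtering keeps >= threshold, passes NA with a warning", {
  scans <- data.frame(sample_id = "S", window_index = 1, replicate_index = 1,
                      mz = c(100, 101, 102), intensity = c(1, 1, 1),
                      snr = c(2.9, 3.0, 3.1))
  kept <- snr_filter(scans, 3.0)
  expect_equal(kept$snr, c(3.0, 3.1))
  expect_identical(snr_filter(scans, 0), scans)
  scans$snr[2] <- NA
  expect_warning(kept <- snr_filter(scans, 3.0), "lack an SNR")
  expect_equal(kept$mz, c(101, 102))
})

test_that("simulated sub-threshold noise peaks are removed, signal retained", {
  cfg <- noise_free(two_window_config(seed = 31, noise_peaks_per_window = 5))
  met <- grid_metabolites(10, 60, 240)
  sim <- simulate_plate(plate_layout(1), met, cfg)
  kept <- snr_filter(sim$scans, 3.0)
  expect_identical(nrow(kept), nrow(sim$scans) - 5L * 2L * 4L)
  expect_true(all(kept$snr >= 3))
  expect_true(all(kept$mz %in% sim$truth$true_mz))
})

test_that("ppm clustering equals brute-force single linkage on random instances", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(2:50, 1)
    mz <- sort(runif(n, 100, 110))
    # random mixture of tight clusters and isolated peaks
    mz <- mz + rep(0, n)
    got <- cluster_mz(mz, ppm = 2)
    want <- oracle_single_linkage(mz, ppm = 2)
    expect_identical(got, as.integer(want))
  }
  # dense case with chaining
  mz <- 100 * (1 + cumsum(runif(40, 0, 4e-6)))
  expect_identical(cluster_mz(mz, 2), as.integer(oracle_single_linkage(mz, 2)))
})

test_that("within-window alignment groups replicates and respects separation", {
  # identical noise-free replicates: one group per peak, count 4
  scans <- do.call(rbind, lapply(1:4, function(r) {
    data.frame(replicate_index = r, mz = c(100, 100.01, 120),
               intensity = c(10, 20, 30))
  }))
  g <- align_within_window(scans, ppm = 2)
  expect_identical(nrow(g), 3L)
  expect_true(all(g$n_replicates == 4L))
  expect_equal(g$mz, c(100, 100.01, 120))
  expect_equal(g$intensity, c(10, 20, 30))
  # two peaks 10 ppm apart at 2 ppm tolerance stay separate
  g2 <- align_within_window(
    data.frame(replicate_index = 1, mz = c(200, 200 * (1 + 10e-6)),
               intensity = c(1, 1)), ppm = 2)
  expect_identical(nrow(g2), 2L)
  # one replicate contributing two close peaks forces a split
  g3 <- align_within_window(
    data.frame(replicate_index = c(1, 1, 2),
               mz = c(300, 300 * (1 + 1e-6), 300 * (1 + 0.4e-6)),
               intensity = c(1, 1, 1)), ppm = 2)
  expect_identical(nrow(g3), 2L)
})

test_that("the 3-of-4 replicate filter applies >= semantics on replicate counts", {
  groups <- data.frame(mz = c(100, 110, 120), intensity = 1,
                       n_replicates = c(3L, 2L, 4L),
                       replicates = c("1;2;3", "1;4", "1;2;3;4"))
  kept <- internal_replicate_filter(groups, min_replicates = 3)
  expect_equal(kept$mz, c(100, 120))
  expect_identical(internal_replicate_filter(groups, 1), groups)
})

test_that("replicate-filtered intensity is the mean over replicates present", {
  scans <- data.frame(replicate_index = c(1, 2, 3), mz = rep(150, 3),
                      intensity = c(90, 100, 110))
  g <- internal_replicate_filter(align_within_window(scans, 2), 3)
  expect_equal(g$intensity, 100)
  expect_identical(g$replicates, "1;2;3")
})

test_that("window stitching keeps each peak exactly once", {
  wins <- cbind(c(50, 140), c(150, 250))
  # interior peak of window 2 only
  g <- data.frame(window_index = 2L, mz = 200, intensity = 1)
  st <- stitch_windows(g, wins)
  expect_identical(nrow(st), 1L)
  # identical peak reported by both windows in the overlap
  g2 <- data.frame(window_index = c(1L, 2L), mz = c(145.0, 145.0),
                   intensity = c(1, 1))
  st2 <- stitch_windows(g2, wins)
  expect_identical(nrow(st2), 1L)
  # straddling the midpoint boundary: deduplicated by ppm proximity
  g3 <- data.frame(window_index = c(1L, 2L),
                   mz = c(145 * (1 - 0.4e-6), 145 * (1 + 0.4e-6)),
                   intensity = c(1, 1))
  st3 <- stitch_windows(g3, wins)
  expect_identical(nrow(st3), 1L)
  expect_identical(attr(st3, "dedup_count"), 1L)
  # edge-margin mode also deduplicates the overlap interior
  st4 <- stitch_windows(g2, wins,
                        process_params(window_trim_mode = "edge_margin",
                                       edge_margin_da = 1))
  expect_identical(nrow(st4), 1L)
})

test_that("cross-sample alignment builds an ordered matrix with missing markers", {
  st <- data.frame(
    sample_id = c("a", "a", "b", "b", "b"),
    mz = c(100, 200, 100.00001, 200.00002, 300),
    intensity = c(1, 2, 3, 4, 5)
  )
  samples <- data.frame(sample_id = c("a", "b"), class = "sample")
  fm <- align_across_samples(st, samples, ppm = 3)
  expect_identical(dim(fm$values), c(2L, 3L))
  expect_false(is.unsorted(fm$features$mz, strictly = TRUE))
  expect_true(is.na(fm$values["a", 3]))
  expect_equal(unname(fm$values["b", ]), c(3, 4, 5))
  # two identical samples give identical columns, no missing
  st2 <- rbind(transform(st[st$sample_id == "a", ]),
               transform(st[st$sample_id == "a", ], sample_id = "b"))
  fm2 <- align_across_samples(st2, samples, ppm = 3)
  expect_false(anyNA(fm2$values))
  expect_equal(fm2$values["a", ], fm2$values["b", ])
})

test_that("cross-sample alignment equals the exhaustive oracle on small instances", {
  set.seed(7)
  for (rep in 1:10) {
    n_samp <- sample(2:5, 1)
    peaks <- do.call(rbind, lapply(seq_len(n_samp), function(s) {
      n <- sample(5:30, 1)
      # enforce within-sample separation so owner splitting never triggers
      mz <- 100 + cumsum(runif(n, 0.01, 3))
      data.frame(sample_id = sprintf("S%d", s), mz = mz,
                 intensity = runif(n, 10, 100))
    }))
    jit <- peaks
    jit$mz <- jit$mz * (1 + runif(nrow(jit), -1e-6, 1e-6))
    samples <- data.frame(sample_id = sprintf("S%d", seq_len(n_samp)),
                          class = "sample")
    fm <- align_across_samples(jit, samples, ppm = 3)
    want <- oracle_single_linkage(jit$mz, 3)
    expect_identical(ncol(fm$values), max(want))
    # feature membership identical: each oracle cluster has one matrix column
    got_col <- integer(nrow(jit))
    for (i in seq_len(nrow(jit))) {
      si <- jit$sample_id[i]
      got_col[i] <- which(abs(fm$values[si, ] - jit$intensity[i]) < 1e-9)[1]
    }
    # same partition: oracle clusters and matrix columns are in bijection
    expect_identical(length(unique(paste(want, got_col))),
                     length(unique(want)))
    expect_identical(length(unique(got_col)), length(unique(want)))
  }
})

test_that("blank filtering removes blank-borne features and drops blank wells", {
  vals <- rbind(c(100, 1000, NA), c(110, 1100, NA), c(100, 10, 50))
  fm <- feature_matrix(
    vals,
    features = data.frame(feature_id = c("cont", "true", "blankonly"),
                          mz = c(100, 200, 300)),
    samples = data.frame(sample_id = c("s1", "s2", "b1"),
                         class = c("sample", "sample", "blank"))
  )
  res <- blank_filter(fm, blank_fold = 10, blank_min_fraction = 1)
  expect_identical(res$fm$features$feature_id, "true")
  expect_setequal(res$report$feature_id, c("cont", "blankonly"))
  expect_false(any(res$fm$samples$class == "blank"))
  # feature absent from all blanks is always retained
  expect_true("true" %in% res$fm$features$feature_id)
  no_blanks <- fm_subset(fm, samples = 1:2)
  expect_error(blank_filter(no_blanks), "skip the blank filter")
})

test_that("a simulated contaminated plate is cleaned without losing true features", {
  cfg <- acquisition_config(technical_cv = 0.05, peak_dropout_prob = 0,
                            mz_jitter_ppm = 0.5, seed = 13)
  met <- metabolite_library(200, n_contaminants = 20, seed = 13)
  lay <- plate_layout(n_samples = 10, n_blank = 3)
  sim <- simulate_plate(lay, met, cfg)
  proc <- process_plate(sim$scans, sim$layout, cfg$window_ranges,
                        process_params(), apply_presence_filter = FALSE)
  cont_mz <- sim$truth$true_mz[sim$truth$metabolite_id %in%
                                 met$id[met$is_contaminant]]
  removed_mz <- proc$blank_report$mz
  expect_identical(nrow(proc$blank_report), 20L)
  expect_true(all(vapply(removed_mz, function(m)
    any(abs(1e6 * (m - cont_mz) / m) < 3), logical(1))))
  expect_identical(ncol(proc$fm$values), 200L)
})

test_that("sample presence filtering applies >= semantics overall and per class", {
  vals <- matrix(1, nrow = 10, ncol = 3)
  vals[1:2, 1] <- NA   # 8/10 = 0.8
  vals[1:3, 2] <- NA   # 7/10 = 0.7
  fm <- feature_matrix(
    vals,
    features = data.frame(feature_id = c("f1", "f2", "f3"), mz = 1:3),
    samples = data.frame(sample_id = sprintf("s%d", 1:10),
                         class = rep(c("sample", "QC"), each = 5))
  )
  kept <- sample_presence_filter(fm, 0.80)
  expect_setequal(kept$features$feature_id, c("f1", "f3"))
  expect_identical(sample_presence_filter(fm, 0), fm)
  # per-class mode: f1 is missing 2/5 in class "sample" (0.6 < 0.8)
  kept2 <- sample_presence_filter(fm, 0.80, per_class = TRUE)
  expect_setequal(kept2$features$feature_id, "f3")
})

test_that("filters are idempotent and tightening parameters never adds features", {
  cfg <- acquisition_config(seed = 17, peak_dropout_prob = 0.15)
  met <- metabolite_library(60, n_contaminants = 5, seed = 17)
  lay <- plate_layout(n_samples = 8, n_blank = 2)
  sim <- simulate_plate(lay, met, cfg)
  counts <- vapply(c(1, 2, 3, 4), function(mr) {
    p <- process_params(min_replicates = mr)
    proc <- process_plate(sim$scans, sim$layout, cfg$window_ranges, p)
    ncol(proc$fm$values)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  proc <- process_plate(sim$scans, sim$layout, cfg$window_ranges)
  once <- sample_presence_filter(proc$fm, 0.8)
  expect_identical(sample_presence_filter(once, 0.8), once)
  expect_identical(sample_presence_filter(sample_presence_filter(once, 0.5), 0.5),
                   sample_presence_filter(once, 0.5))
})

test_that("permuting sample order permutes matrix rows only", {
  cfg <- noise_free(two_window_config(seed = 19))
  met <- grid_metabolites(12, 60, 240)
  lay <- plate_layout(n_samples = 4)
  sim <- simulate_plate(lay, met, cfg)
  proc1 <- process_plate(sim$scans, sim$layout, cfg$window_ranges)
  perm <- sim$layout[c(3, 1, 4, 2), ]
  proc2 <- process_plate(sim$scans, perm, cfg$window_ranges)
  expect_equal(proc1$fm$features, proc2$fm$features)
  expect_equal(proc2$fm$values,
               proc1$fm$values[proc2$fm$samples$sample_id, ])
})
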