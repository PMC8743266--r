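# Core processing: internal scan-replicate alignment, the 3-of-4
# replicate filter, SIM-window stitching, cross-sample alignment, blank
# subtraction and sample-presence filtering.

#' Processing parameters
#'
#' Defaults fixed and documented by this package (the acquisition
#' literature leaves them to its tooling): SNR threshold 3, 2 ppm
#' within-sample and 3 ppm across-sample alignment, peaks required in at
#' least 3 of 4 internal scan replicates, 10-fold blank threshold, 80%
#' sample-presence threshold.
#'
#' @param snr_threshold minimum signal-to-noise ratio (peaks with
#'   `snr >= threshold` are kept).
#' @param align_ppm m/z clustering tolerance across internal scan
#'   replicates (ppm, on the log-m/z scale).
#' @param across_ppm m/z clustering tolerance across samples (ppm).
#' @param min_replicates,n_replicates a peak must appear in at least
#'   `min_replicates` of the `n_replicates` internal scans.
#' @param window_trim_mode `"midpoint"` (split each overlap at its
#'   midpoint) or `"edge_margin"` (discard `edge_margin_da` Da from each
#'   shared window edge).
#' @param edge_margin_da margin for `"edge_margin"` trimming, in Da.
#' @param blank_fold a feature must be `blank_fold` times more intense in
#'   samples than in blanks to survive the blank filter.
#' @param blank_min_fraction fraction of blank wells a feature must occur
#'   in before it counts as blank-borne.
#' @param presence_fraction minimum non-missing fraction per feature.
#' @param presence_per_class apply the presence threshold within every
#'   class rather than over all samples.
#' @return object of class `process_params`.
#' @export
process_params <- function(snr_threshold = 3.0, align_ppm = 2.0,
                           across_ppm = 3.0, min_replicates = 3L,
                           n_replicates = 4L,
                           window_trim_mode = c("midpoint", "edge_margin"),
                           edge_margin_da = 2.0, blank_fold = 10.0,
                           blank_min_fraction = 1.0,
                           presence_fraction = 0.80,
                           presence_per_class = FALSE) {
  window_trim_mode <- match.arg(window_trim_mode)
  stopifnot(min_replicates >= 1, min_replicates <= n_replicates,
            align_ppm > 0, across_ppm > 0,
            presence_fraction >= 0, presence_fraction <= 1,
            blank_fold >= 1, blank_min_fraction > 0, blank_min_fraction <= 1,
            edge_margin_da >= 0)
  structure(list(snr_threshold = snr_threshold, align_ppm = align_ppm,
                 across_ppm = across_ppm,
                 min_replicates = as.integer(min_replicates),
                 n_replicates = as.integer(n_replicates),
                 window_trim_mode = window_trim_mode,
                 edge_margin_da = edge_margin_da, blank_fold = blank_fold,
                 blank_min_fraction = blank_min_fraction,
                 presence_fraction = presence_fraction,
                 presence_per_class = presence_per_class),
            class = "process_params")
}

#' Signal-to-noise filter
#'
#' Removes peaks with `snr < threshold` (`>=` is kept, so a peak exactly
#' at the threshold survives). Peaks without an SNR value are retained
#' with a warning.
#'
#' @param scans long peak table.
#' @param threshold minimum SNR.
#' @return the filtered peak table, order preserved.
#' @export
snr_filter <- function(scans, threshold = 3.0) {
  if (threshold <= 0) return(scans)
  no_snr <- is.na(scans$snr)
  if (any(no_snr)) {
    warning(sum(no_snr), " peak(s) lack an SNR value and were retained",
            call. = FALSE)
  }
  scans[no_snr | scans$snr >= threshold, , drop = FALSE]
}

# ppm-scale coordinate: differences of 1e6*log(mz) are ppm distances
.ppm_coord <- function(mz) 1e6 * log(mz)

#' Single-linkage m/z clustering with a ppm cut
#'
#' Peaks are sorted by m/z and split wherever the gap between neighbours
#' exceeds `ppm` (distances measured on the log-m/z scale, where they are
#' symmetric) -- exactly single-linkage clustering cut at `ppm`. When an
#' `owner` (scan replicate or sample) contributes more than one peak to a
#' group, the group is recursively split at its largest internal gap.
#'
#' @param mz numeric m/z vector.
#' @param ppm tolerance.
#' @param owner optional vector; no group will contain two peaks of one
#'   owner.
#' @return integer group ids (1-based, in ascending m/z order of group
#'   centres), aligned with the input order.
#' @export
cluster_mz <- function(mz, ppm, owner = NULL) {
  n <- length(mz)
  if (n == 0) return(integer(0))
  o <- order(mz)
  u <- .ppm_coord(mz[o])
  ow <- if (is.null(owner)) NULL else owner[o]
  grp <- cumsum(c(1L, as.integer(diff(u) > ppm)))
  if (!is.null(ow)) {
    repeat {
      dup_grp <- unique(grp[duplicated(paste(grp, ow))])
      if (!length(dup_grp)) break
      for (g in dup_grp) {
        idx <- which(grp == g)
        gaps <- diff(u[idx])
        cut <- which.max(gaps)
        grp[idx[(cut + 1):length(idx)]] <- max(grp) + 1L
      }
      # renumber in m/z order
      grp <- match(grp, unique(grp))
      grp <- as.integer(grp)
    }
  }
  res <- integer(n)
  res[o] <- grp
  res
}

#' Align peaks across internal scan replicates of one window
#'
#' @param scans peak rows of one (sample, window): columns
#'   `replicate_index`, `mz`, `intensity`.
#' @param ppm clustering tolerance.
#' @return data.frame of peak groups: intensity-weighted `mz`,
#'   `intensity` (mean over the replicates in which the group occurs),
#'   `n_replicates`, and `replicates` (`;`-joined indices).
#' @export
align_within_window <- function(scans, ppm = 2.0) {
  if (nrow(scans) == 0) {
    return(data.frame(mz = numeric(0), intensity = numeric(0),
                      n_replicates = integer(0), replicates = character(0)))
  }
  g <- cluster_mz(scans$mz, ppm, owner = scans$replicate_index)
  mz <- vapply(split(seq_len(nrow(scans)), g), function(i) {
    stats::weighted.mean(scans$mz[i], scans$intensity[i])
  }, numeric(1))
  intensity <- vapply(split(scans$intensity, g), mean, numeric(1))
  reps <- split(scans$replicate_index, g)
  out <- data.frame(
    mz = mz, intensity = intensity,
    n_replicates = vapply(reps, function(r) length(unique(r)), integer(1)),
    replicates = vapply(reps, function(r)
      paste(sort(unique(r)), collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$mz), ]
  rownames(out) <- NULL
  out
}

#' Internal scan-replicate filter
#'
#' Retains peak groups present in at least `min_replicates` of the
#' internal scan replicates (the 3-of-4 rule at the defaults). Group
#' intensity is already the mean over the replicates in which the peak
#' occurs.
#'
#' @param groups output of [align_within_window()].
#' @param min_replicates minimum replicate count.
#' @return filtered groups.
#' @export
internal_replicate_filter <- function(groups, min_replicates = 3L) {
  groups[groups$n_replicates >= min_replicates, , drop = FALSE]
}

#' Stitch overlapping SIM windows into one peak list
#'
#' Each window keeps only the part of its range assigned by the trim
#' mode: at `"midpoint"` every overlap is split at its midpoint and each
#' window keeps its own side; at `"edge_margin"` a fixed margin is
#' discarded from each shared window edge and any peak still reported by
#' both windows is deduplicated by ppm proximity (ties broken toward the
#' window whose centre is nearer the peak, then toward the lower index).
#'
#' @param window_groups data.frame with `window_index`, `mz`,
#'   `intensity` (replicate-filtered groups of one sample).
#' @param window_ranges two-column matrix of window ranges.
#' @param params a [process_params()].
#' @return stitched peak list sorted by m/z, with a `dedup_count`
#'   attribute counting cross-window duplicates removed.
#' @export
stitch_windows <- function(window_groups, window_ranges,
                           params = process_params()) {
  wins <- as.matrix(window_ranges)
  nw <- nrow(wins)
  lo_eff <- wins[, 1]
  hi_eff <- wins[, 2]
  if (nw > 1) {
    for (i in seq_len(nw - 1)) {
      if (params$window_trim_mode == "midpoint") {
        mid <- (wins[i + 1, 1] + wins[i, 2]) / 2
        hi_eff[i] <- mid
        lo_eff[i + 1] <- mid
      } else {
        hi_eff[i] <- wins[i, 2] - params$edge_margin_da
        lo_eff[i + 1] <- wins[i + 1, 1] + params$edge_margin_da
      }
    }
  }
  g <- window_groups
  wi <- g$window_index
  # each window keeps only its effective range; a peak landing exactly on a
  # shared boundary survives in both windows and is deduplicated below
  keep <- g$mz >= lo_eff[wi] & g$mz <= hi_eff[wi]
  g <- g[keep, , drop = FALSE]
  dedup <- 0L
  if (nrow(g) > 1) {
    cl <- cluster_mz(g$mz, params$align_ppm)
    if (anyDuplicated(cl)) {
      keep_idx <- vapply(split(seq_len(nrow(g)), cl), function(idx) {
        if (length(idx) == 1) return(idx)
        centre <- rowMeans(wins)[g$window_index[idx]]
        d <- abs(g$mz[idx] - centre)
        idx[order(d, g$window_index[idx])][1]
      }, integer(1))
      dedup <- nrow(g) - length(keep_idx)
      g <- g[sort(keep_idx), , drop = FALSE]
    }
  }
  g <- g[order(g$mz), , drop = FALSE]
  rownames(g) <- NULL
  attr(g, "dedup_count") <- dedup
  g
}

#' Align stitched peak lists across samples into a feature matrix
#'
#' Single-linkage ppm clustering over the pooled peaks of all samples
#' (no sample contributes two peaks to one feature); unmatched peaks
#' become features with missing values in the other samples.
#'
#' @param stitched data.frame with `sample_id`, `mz`, `intensity` pooled
#'   over samples.
#' @param samples per-sample metadata data.frame (`sample_id`, `class`,
#'   ...), one row per sample in `stitched`.
#' @param ppm clustering tolerance (default 3).
#' @return a [feature_matrix()].
#' @export
align_across_samples <- function(stitched, samples, ppm = 3.0) {
  stopifnot(nrow(samples) >= 1,
            all(stitched$sample_id %in% samples$sample_id))
  g <- cluster_mz(stitched$mz, ppm, owner = stitched$sample_id)
  ng <- max(g, 0L)
  mz <- vapply(split(seq_len(nrow(stitched)), g), function(i) {
    stats::weighted.mean(stitched$mz[i], stitched$intensity[i])
  }, numeric(1))
  spread <- vapply(split(stitched$mz, g), function(m) {
    if (length(m) < 2) 0 else 1e6 * (max(m) - min(m)) / mean(m)
  }, numeric(1))
  o <- order(mz)
  rank <- match(seq_len(ng), o)
  vals <- matrix(NA_real_, nrow = nrow(samples), ncol = ng,
                 dimnames = list(samples$sample_id, NULL))
  si <- match(stitched$sample_id, samples$sample_id)
  vals[cbind(si, rank[g])] <- stitched$intensity
  features <- data.frame(
    feature_id = sprintf("F%05d", seq_len(ng)),
    mz = mz[o], mz_spread_ppm = spread[o], stringsAsFactors = FALSE
  )
  feature_matrix(vals, features, samples)
}

#' Blank (extraction-control) filter
#'
#' A feature is removed when it occurs in at least `blank_min_fraction`
#' of the blank wells and its mean intensity over non-blank samples is
#' below `blank_fold` times its mean over the blanks in which it occurs.
#' Blank samples are dropped from the returned matrix.
#'
#' @param fm a [feature_matrix()] containing blank-class samples.
#' @param blank_fold,blank_min_fraction see [process_params()].
#' @return list: `fm` (filtered, blanks removed) and `report`
#'   (data.frame of removed features with both means).
#' @export
blank_filter <- function(fm, blank_fold = 10.0, blank_min_fraction = 1.0) {
  bi <- which(fm$samples$class == "blank")
  if (!length(bi)) {
    stop("no blank samples in the matrix; skip the blank filter explicitly ",
         "rather than calling it without blanks", call. = FALSE)
  }
  oi <- setdiff(seq_len(nrow(fm$values)), bi)
  bv <- fm$values[bi, , drop = FALSE]
  ov <- fm$values[oi, , drop = FALSE]
  in_blank_frac <- colMeans(!is.na(bv))
  mean_blank <- suppressWarnings(colMeans(bv, na.rm = TRUE))      # NaN if absent
  mean_other <- suppressWarnings(colMeans(ov, na.rm = TRUE))
  mean_other[is.nan(mean_other)] <- 0                              # absent from samples
  remove <- in_blank_frac >= blank_min_fraction &
    !is.nan(mean_blank) & mean_other < blank_fold * mean_blank
  report <- data.frame(
    feature_id = fm$features$feature_id[remove],
    mz = fm$features$mz[remove],
    mean_blank = mean_blank[remove],
    mean_sample = mean_other[remove],
    blank_fraction = in_blank_frac[remove],
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  fm2 <- fm_subset(fm, features = !remove, samples = oi)
  list(fm = fm2, report = report)
}

#' Sample-presence filter
#'
#' Retains features observed (non-missing) in at least
#' `presence_fraction` of samples -- overall, or within every class when
#' `per_class` is set.
#'
#' @param fm a [feature_matrix()].
#' @param presence_fraction minimum presence (`>=` is kept).
#' @param per_class require the threshold within each class.
#' @return the filtered matrix.
#' @export
sample_presence_filter <- function(fm, presence_fraction = 0.80,
                                   per_class = FALSE) {
  if (presence_fraction <= 0) return(fm)
  pres <- if (per_class) {
    cls <- split(seq_len(nrow(fm$values)), fm$samples$class)
    do.call(pmin, lapply(cls, function(i)
      colMeans(!is.na(fm$values[i, , drop = FALSE]))))
  } else {
    colMeans(!is.na(fm$values))
  }
  fm_subset(fm, features = pres >= presence_fraction)
}

#' Full per-plate processing: scans to feature matrix
#'
#' Runs SNR filtering, within-window scan-replicate alignment, the
#' replicate filter, window stitching, cross-sample alignment, then (when
#' blanks are present) the blank filter and finally the sample-presence
#' filter. Per-stage peak/feature counts are logged.
#'
#' @param scans long peak table (simulator output or [read_peaklists()]).
#' @param samples per-sample metadata (`sample_id`, `class`, ...); plate
#'   layouts from [simulate_plate()] can be passed directly.
#' @param window_ranges SIM window ranges used in acquisition.
#' @param params a [process_params()].
#' @param apply_blank_filter apply the blank filter when blanks are
#'   present (default TRUE).
#' @param apply_presence_filter apply the sample-presence filter
#'   (default TRUE).
#' @return list of class `dims_processing`: `fm` (the final
#'   [feature_matrix()]), `blank_report`, `stage_log` (named counts).
#' @export
process_plate <- function(scans, samples, window_ranges,
                          params = process_params(),
                          apply_blank_filter = TRUE,
                          apply_presence_filter = TRUE) {
  if ("well" %in% names(samples) && !"sample_id" %in% names(samples)) {
    samples <- as_plate_layout(samples)
  }
  samples <- samples[samples$class != "empty", , drop = FALSE]
  samples <- samples[samples$sample_id %in% unique(scans$sample_id), ,
                     drop = FALSE]
  log <- c(raw_peaks = nrow(scans))
  scans <- snr_filter(scans, params$snr_threshold)
  log["snr_filtered_peaks"] <- nrow(scans)

  stitched <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    s <- scans[scans$sample_id == sid, , drop = FALSE]
    per_win <- lapply(sort(unique(s$window_index)), function(wi) {
      grp <- align_within_window(s[s$window_index == wi, , drop = FALSE],
                                 params$align_ppm)
      grp <- internal_replicate_filter(grp, params$min_replicates)
      if (nrow(grp)) grp$window_index <- wi
      grp
    })
    wg <- do.call(rbind, per_win[vapply(per_win, nrow, integer(1)) > 0])
    if (is.null(wg) || nrow(wg) == 0) {
      stitched[[i]] <- NULL
      next
    }
    st <- stitch_windows(wg, window_ranges, params)
    st$sample_id <- sid
    stitched[[i]] <- st[c("sample_id", "mz", "intensity")]
  }
  stitched <- do.call(rbind, stitched)
  log["stitched_peaks"] <- if (is.null(stitched)) 0L else nrow(stitched)
  if (is.null(stitched) || nrow(stitched) == 0) {
    stop("no peaks survived replicate filtering", call. = FALSE)
  }
  fm <- align_across_samples(stitched, samples, params$across_ppm)
  log["aligned_features"] <- ncol(fm$values)

  blank_report <- NULL
  if (apply_blank_filter && any(fm$samples$class == "blank")) {
    bf <- blank_filter(fm, params$blank_fold, params$blank_min_fraction)
    fm <- bf$fm
    blank_report <- bf$report
    log["post_blank_features"] <- ncol(fm$values)
  }
  if (apply_presence_filter) {
    fm <- sample_presence_filter(fm, params$presence_fraction,
                                 params$presence_per_class)
    log["post_presence_features"] <- ncol(fm$values)
  }
  structure(list(fm = fm, blank_report = blank_report, stage_log = log),
            class = "dims_processing")
}

#' @export
print.dims_processing <- function(x, ...) {
  cat("dims_processing stages:\n")
  for (nm in names(x$stage_log)) {
    cat(sprintf("  %-24s %d\n", nm, x$stage_log[[nm]]))
  }
  print(x$fm)
  invisible(x)
}
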