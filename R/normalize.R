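# Normalisation, QC-based drift correction and the repeatability
# assessment framework (RSD / median RSD per sample class).

#' Probabilistic quotient normalisation (PQN)
#'
#' Each sample is divided by the median of its per-feature quotients
#' against a reference spectrum. The reference defaults to the per-feature
#' median over pooled-QC samples (the natural dilution reference when QCs
#' exist) and falls back to the median over all samples.
#'
#' @param fm a [feature_matrix()].
#' @param reference `"median_of_QCs"` or `"median_of_all"`.
#' @param qc_class class label of QC samples.
#' @param min_shared_features warn when a sample shares fewer features
#'   than this with the reference (default 10).
#' @return list: `fm` (normalised; missing stays missing) and `factors`
#'   (named per-sample quotient factors).
#' @export
pqn_normalize <- function(fm, reference = c("median_of_QCs", "median_of_all"),
                          qc_class = "QC", min_shared_features = 10L) {
  reference <- match.arg(reference)
  v <- fm$values
  if (reference == "median_of_QCs" && !any(fm$samples$class == qc_class)) {
    reference <- "median_of_all"
  }
  ri <- if (reference == "median_of_QCs") .class_idx(fm, qc_class)
        else seq_len(nrow(v))
  ref <- apply(v[ri, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  usable <- !is.na(ref) & ref > 0
  if (!any(usable)) stop("reference spectrum is entirely missing", call. = FALSE)
  factors <- vapply(seq_len(nrow(v)), function(i) {
    q <- v[i, usable] / ref[usable]
    q <- q[!is.na(q)]
    if (length(q) < min_shared_features) {
      warning("sample '", fm$samples$sample_id[i], "' shares only ",
              length(q), " features with the reference", call. = FALSE)
    }
    if (!length(q)) return(1)
    stats::median(q)
  }, numeric(1))
  names(factors) <- fm$samples$sample_id
  fm$values <- v / factors
  list(fm = fm, factors = factors)
}

#' QC-anchored signal-drift correction
#'
#' Fits a smooth trend (loess or smoothing spline) through the QC
#' intensities of every feature as a function of injection order, divides
#' all samples by the trend evaluated at their own injection order, and
#' rescales to the feature's QC median. Features with fewer than
#' `min_qc` non-missing QC values pass through uncorrected (counted in
#' the `uncorrected` attribute).
#'
#' @param fm a [feature_matrix()]; `samples` must carry
#'   `injection_order`.
#' @param qc_class class label of QC samples (>= 4 QC injections
#'   required).
#' @param method `"loess"` (degree-1 local regression, the default) or
#'   `"spline"`.
#' @param span loess span (fraction of QC points; default 0.75).
#' @param min_qc minimum non-missing QC values per feature (default 4).
#' @return the corrected [feature_matrix()] with attribute
#'   `uncorrected` (number of pass-through features).
#' @export
drift_correct <- function(fm, qc_class = "QC", method = c("loess", "spline"),
                          span = 0.75, min_qc = 4L) {
  method <- match.arg(method)
  if (!"injection_order" %in% names(fm$samples) ||
      anyNA(fm$samples$injection_order)) {
    stop("sample metadata must carry a complete injection_order column",
         call. = FALSE)
  }
  qi <- .class_idx(fm, qc_class)
  if (length(qi) < 4) stop("need >= 4 QC injections for drift correction",
                           call. = FALSE)
  ord <- fm$samples$injection_order
  v <- fm$values
  uncorrected <- 0L
  for (j in seq_len(ncol(v))) {
    y <- v[qi, j]
    ok <- !is.na(y)
    if (sum(ok) < min_qc) {
      uncorrected <- uncorrected + 1L
      next
    }
    x <- ord[qi][ok]
    y <- y[ok]
    fit <- switch(method,
      loess = stats::loess(y ~ x, span = span, degree = 1,
                           control = stats::loess.control(surface = "direct")),
      spline = stats::smooth.spline(x, y, df = min(4, sum(ok) - 1)))
    trend <- if (method == "loess") {
      stats::predict(fit, newdata = data.frame(x = ord))
    } else {
      stats::predict(fit, ord)$y
    }
    trend[trend <= 0 | !is.finite(trend)] <- NA
    scale <- stats::median(y)
    v[, j] <- v[, j] / trend * scale
  }
  if (uncorrected > 0) {
    message(uncorrected, " feature(s) had < ", min_qc,
            " QC values and were not drift-corrected")
  }
  fm$values <- v
  attr(fm, "uncorrected") <- uncorrected
  fm
}

#' Relative standard deviation (percent)
#'
#' `100 * sd / mean` over non-missing values, using the sample (n-1)
#' standard deviation. Returns `NA` (an explicit undefined marker, never
#' 0) with fewer than two non-missing values or a non-positive mean.
#'
#' @param values numeric vector.
#' @return RSD in percent, or `NA` when undefined.
#' @export
rsd <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (m <= 0) return(NA_real_)
  100 * stats::sd(x) / m
}

# per-feature RSDs over a set of sample rows
.feature_rsds <- function(fm, idx) {
  apply(fm$values[idx, , drop = FALSE], 2, rsd)
}

#' QC-based reliability filter
#'
#' Discards features whose RSD across the QC samples exceeds `threshold`
#' percent or is undefined (a feature at exactly the threshold is kept,
#' matching `<=` semantics).
#'
#' @param fm a [feature_matrix()].
#' @param qc_class class label of QC samples (>= 2 required).
#' @param threshold RSD threshold in percent (default 30).
#' @return the filtered matrix.
#' @export
qc_rsd_filter <- function(fm, qc_class = "QC", threshold = 30) {
  qi <- .class_idx(fm, qc_class)
  if (length(qi) < 2) stop("need >= 2 QC samples for the RSD filter",
                           call. = FALSE)
  r <- .feature_rsds(fm, qi)
  fm_subset(fm, features = !is.na(r) & r <= threshold)
}

#' Repeatability assessment (QC report)
#'
#' Computes, per sample group, the sample count, feature count at the
#' presence threshold, count of features with RSD at or below
#' `rsd_feature_threshold`, and the median RSD (mRSD), with pass/fail
#' flags against the configured mRSD targets. Groupings mirror common
#' plate-qualification designs: QC repeatability, intra-plate edge vs
#' centre wells, and inter-plate comparisons.
#'
#' @param fm a [feature_matrix()].
#' @param grouping `"qc"`, `"intra_plate_edge_vs_centre"`,
#'   `"inter_plate"`, or the name of a metadata column to group by.
#' @param presence_fraction feature presence threshold applied within
#'   each group before counting (default 0.8).
#' @param rsd_feature_threshold per-feature RSD threshold in percent
#'   (default 30).
#' @param biological_mrsd_max mRSD target for biological classes
#'   (default 30).
#' @param qc_mrsd_max mRSD target for QC groups (default 20).
#' @return data.frame of class `qc_report`, one row per group.
#' @export
assess_repeatability <- function(fm, grouping = "qc",
                                 presence_fraction = 0.8,
                                 rsd_feature_threshold = 30,
                                 biological_mrsd_max = 30,
                                 qc_mrsd_max = 20) {
  s <- fm$samples
  groups <- switch(grouping,
    qc = {
      idx <- which(s$class == "QC")
      if (!length(idx)) stop("no QC samples present", call. = FALSE)
      list(QC = idx)
    },
    intra_plate_edge_vs_centre = {
      if (!"position_class" %in% names(s)) {
        stop("grouping needs a position_class column; available: ",
             paste(names(s), collapse = ", "), call. = FALSE)
      }
      idx <- which(s$class == "sample")
      split(idx, s$position_class[idx])
    },
    inter_plate = {
      if (!"plate_id" %in% names(s)) {
        stop("grouping needs a plate_id column; available: ",
             paste(names(s), collapse = ", "), call. = FALSE)
      }
      idx <- which(s$class == "sample")
      split(idx, s$plate_id[idx])
    },
    {
      if (!grouping %in% names(s)) {
        stop("unknown grouping '", grouping, "'; available fields: ",
             paste(names(s), collapse = ", "), call. = FALSE)
      }
      split(seq_len(nrow(s)), s[[grouping]])
    })
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    pres <- colMeans(!is.na(fm$values[idx, , drop = FALSE]))
    feat <- pres >= presence_fraction
    r <- .feature_rsds(fm, idx)[feat]
    mrsd <- stats::median(r, na.rm = TRUE)
    is_qc <- grouping == "qc" || all(s$class[idx] == "QC")
    target <- if (is_qc) qc_mrsd_max else biological_mrsd_max
    data.frame(group = g, n_samples = length(idx),
               feature_count = sum(feat),
               count_rsd_le_threshold = sum(r <= rsd_feature_threshold,
                                            na.rm = TRUE),
               mrsd = mrsd, mrsd_target = target,
               pass = !is.na(mrsd) && mrsd < target,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("qc_report", class(out))
  attr(out, "grouping") <- grouping
  attr(out, "rsd_feature_threshold") <- rsd_feature_threshold
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (grouping: ", attr(x, "grouping"), ")\n", sep = "")
  df <- as.data.frame(x)
  df$mrsd <- sprintf("%.1f%%", df$mrsd)
  df$pass <- ifelse(df$pass, "PASS", "FAIL")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialise a QC report as TSV plus a text summary
#'
#' @param report a `qc_report` from [assess_repeatability()].
#' @param path output TSV path; a `.txt` summary is written alongside.
#' @param overwrite replace existing files?
#' @export
write_qc_report <- function(report, path, overwrite = FALSE) {
  .check_overwrite(path, overwrite)
  .write_tsv(as.data.frame(report), path,
             header_lines = paste0("grouping=", attr(report, "grouping")))
  txt <- sub("\\.tsv$", ".txt", path)
  con <- file(txt, "wt")
  on.exit(close(con))
  writeLines(utils::capture.output(print(report)), con)
  invisible(path)
}
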