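#' Construct a feature matrix
#'
#' The central container of the pipeline: an aligned samples x features
#' intensity grid plus per-feature and per-sample metadata. Missing
#' intensities are `NA` and are distinct from zero throughout the pipeline
#' (dropout is missingness, not absence of signal).
#'
#' @param values numeric matrix, samples in rows, features in columns;
#'   `NA` marks a missing measurement.
#' @param features data.frame with one row per feature; must contain
#'   `feature_id` (unique) and `mz` (representative m/z, strictly
#'   increasing). An `mz_spread_ppm` column is added if absent.
#' @param samples data.frame with one row per sample; must contain
#'   `sample_id` (unique) and `class` (e.g. `"sample"`, `"QC"`, `"blank"`).
#'   Typical further columns: `plate_id`, `well`, `position_class`,
#'   `injection_order`, `exposure`, `time_h`.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, features, samples) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.data.frame(features), is.data.frame(samples))
  if (!all(c("feature_id", "mz") %in% names(features))) {
    stop("features must have columns feature_id and mz", call. = FALSE)
  }
  if (!all(c("sample_id", "class") %in% names(samples))) {
    stop("samples must have columns sample_id and class", call. = FALSE)
  }
  if (nrow(samples) != nrow(values) || nrow(features) != ncol(values)) {
    stop("values must be samples x features (", nrow(samples), " x ",
         nrow(features), "), got ", nrow(values), " x ", ncol(values),
         call. = FALSE)
  }
  if (anyDuplicated(features$feature_id)) stop("duplicate feature_id", call. = FALSE)
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id", call. = FALSE)
  if (is.unsorted(features$mz, strictly = TRUE)) {
    o <- order(features$mz)
    features <- features[o, , drop = FALSE]
    values <- values[, o, drop = FALSE]
    if (is.unsorted(features$mz, strictly = TRUE)) {
      stop("feature m/z values must be strictly increasing after sorting ",
           "(duplicated representative m/z?)", call. = FALSE)
    }
  }
  if (!"mz_spread_ppm" %in% names(features)) features$mz_spread_ppm <- 0
  if (any(values <= 0, na.rm = TRUE)) {
    stop("intensities must be positive; encode missing as NA, not 0",
         call. = FALSE)
  }
  dimnames(values) <- list(samples$sample_id, features$feature_id)
  rownames(features) <- NULL
  rownames(samples) <- NULL
  structure(list(values = values, features = features, samples = samples),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix: ", nrow(x$values), " samples x ", ncol(x$values),
      " features\n", sep = "")
  cat("  m/z range: ", format(min(x$features$mz), digits = 8), " - ",
      format(max(x$features$mz), digits = 8), "\n", sep = "")
  cat("  classes: ",
      paste(sprintf("%s (%d)", names(table(x$samples$class)),
                    table(x$samples$class)), collapse = ", "), "\n", sep = "")
  miss <- mean(is.na(x$values))
  cat("  missing: ", sprintf("%.1f%%", 100 * miss), "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Subset a feature matrix by features and/or samples
#'
#' @param fm a [feature_matrix()].
#' @param features logical/integer index over features, or feature ids.
#' @param samples logical/integer index over samples, or sample ids.
#' @return the subset `feature_matrix`.
#' @export
fm_subset <- function(fm, features = NULL, samples = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  fi <- seq_len(ncol(fm$values))
  si <- seq_len(nrow(fm$values))
  if (!is.null(features)) {
    fi <- if (is.character(features)) match(features, fm$features$feature_id) else fi[features]
    if (anyNA(fi)) stop("unknown feature id(s)", call. = FALSE)
  }
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, fm$samples$sample_id) else si[samples]
    if (anyNA(si)) stop("unknown sample id(s)", call. = FALSE)
  }
  feature_matrix(fm$values[si, fi, drop = FALSE],
                 fm$features[fi, , drop = FALSE],
                 fm$samples[si, , drop = FALSE])
}

# internal: indices of samples of one class (error when required and absent)
.class_idx <- function(fm, class, required = TRUE) {
  idx <- which(fm$samples$class == class)
  if (required && length(idx) == 0) {
    stop("no samples of class '", class, "' in the matrix (available: ",
         paste(unique(fm$samples$class), collapse = ", "), ")", call. = FALSE)
  }
  idx
}
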