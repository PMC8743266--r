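# Pilot-study statistics: KNN imputation (for PCA only -- hypothesis
# tests run on non-imputed values), generalised-log transform, PCA,
# robust outlier flagging, per-feature one-way ANOVA with
# Benjamini-Hochberg FDR control, Tukey-Kramer post-hoc tests for
# unbalanced designs, and time-course summaries.

#' K-nearest-neighbour imputation over features
#'
#' Missing cells are replaced by the distance-weighted mean of the `k`
#' nearest features (Euclidean distance on jointly observed samples,
#' normalised per shared sample). Neighbourhoods are over features
#' because DIMS matrices have far more features than samples. Observed
#' values are never modified.
#'
#' @param fm a [feature_matrix()] or a numeric samples x features matrix.
#' @param k neighbourhood size (default 5).
#' @return the completed object (same type as the input).
#' @export
impute_knn <- function(fm, k = 5L) {
  is_fm <- inherits(fm, "feature_matrix")
  v <- if (is_fm) fm$values else as.matrix(fm)
  if (!anyNA(v)) return(fm)
  stopifnot(k >= 1)
  if (any(colSums(!is.na(v)) == 0)) {
    stop("feature(s) with no observed values; apply a presence filter first",
         call. = FALSE)
  }
  if (any(rowSums(!is.na(v)) == 0)) {
    stop("sample(s) with no observed values", call. = FALSE)
  }
  X <- t(v)                                  # features x samples
  M <- !is.na(X)
  A <- X; A[!M] <- 0
  B <- A^2
  Mn <- M * 1
  shared <- Mn %*% t(Mn)
  d2 <- B %*% t(Mn) + Mn %*% t(B) - 2 * A %*% t(A)
  msd <- d2 / shared                          # mean squared difference
  msd[shared == 0] <- Inf
  diag(msd) <- Inf
  msd[msd < 0] <- 0                           # numerical noise
  miss <- which(!M, arr.ind = TRUE)
  for (r in seq_len(nrow(miss))) {
    j <- miss[r, 1]; i <- miss[r, 2]
    cand <- which(M[, i])
    if (!length(cand)) {                      # nothing observed at this sample
      X[j, i] <- mean(X[j, M[j, ]])
      next
    }
    d <- sqrt(msd[j, cand])
    o <- order(d)[seq_len(min(k, length(cand)))]
    dd <- d[o]
    w <- if (any(dd == 0)) as.numeric(dd == 0) else 1 / dd
    X[j, i] <- sum(w * X[cand[o], i]) / sum(w)
  }
  out <- t(X)
  if (is_fm) {
    fm$values <- out
    fm
  } else out
}

#' Generalised logarithm transform
#'
#' `x -> ln((x + sqrt(x^2 + lambda)) / 2)`, a variance-stabilising
#' transform that behaves like `ln(x)` for large `x` and is linear near
#' zero. `lambda` can be fixed, or estimated as the median per-feature
#' variance of the pooled-QC technical replicates (falling back to the
#' lowest-intensity decile of features when no QCs exist).
#'
#' @param fm a [feature_matrix()] or numeric matrix (complete,
#'   post-imputation, for downstream PCA).
#' @param lambda `"estimated"` or a non-negative number.
#' @param qc_class QC class label used for estimation.
#' @return transformed object of the input type, with the `lambda` used
#'   attached as an attribute.
#' @export
glog_transform <- function(fm, lambda = "estimated", qc_class = "QC") {
  is_fm <- inherits(fm, "feature_matrix")
  v <- if (is_fm) fm$values else as.matrix(fm)
  if (identical(lambda, "estimated")) {
    lambda <- .estimate_glog_lambda(v, if (is_fm) fm$samples$class else NULL,
                                    qc_class)
  }
  stopifnot(is.numeric(lambda), length(lambda) == 1)
  if (lambda < 0) stop("glog lambda must be >= 0", call. = FALSE)
  g <- log((v + sqrt(v^2 + lambda)) / 2)
  if (is_fm) {
    fm$values <- g
    attr(fm, "glog_lambda") <- lambda
    fm
  } else structure(g, glog_lambda = lambda)
}

.estimate_glog_lambda <- function(v, classes, qc_class) {
  # lambda targets the additive-noise floor, estimated from the technical
  # variance of the lowest-intensity decile of features (QC replicates
  # when available, all samples otherwise)
  mu <- colMeans(v, na.rm = TRUE)
  low <- mu <= stats::quantile(mu, 0.1, na.rm = TRUE)
  rows <- if (!is.null(classes) && sum(classes == qc_class, na.rm = TRUE) >= 3)
    which(classes == qc_class) else seq_len(nrow(v))
  lam <- stats::median(apply(v[rows, low, drop = FALSE], 2, stats::var,
                             na.rm = TRUE), na.rm = TRUE)
  if (!is.finite(lam) || lam < 0) lam <- 0
  lam
}

#' Principal component analysis via singular value decomposition
#'
#' Component signs follow a fixed convention: the largest-magnitude
#' loading of every component is positive, so scores are reproducible
#' across platforms.
#'
#' @param x complete numeric samples x features matrix (a
#'   [feature_matrix()]'s `values` also works).
#' @param n_components number of components to return.
#' @param center subtract feature means first (default TRUE; pass FALSE
#'   for data already mean-centred).
#' @return list: `scores` (samples x components), `loadings`
#'   (features x components), `explained_variance` (fractions,
#'   non-increasing).
#' @export
pca_scores <- function(x, n_components = 2L, center = TRUE) {
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  if (anyNA(x)) stop("PCA needs a complete matrix; impute first", call. = FALSE)
  if (center) x <- sweep(x, 2, colMeans(x))
  s <- svd(x)
  k <- min(n_components, length(s$d))
  flip <- vapply(seq_len(k), function(i) {
    l <- s$v[, i]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(s$u[, seq_len(k), drop = FALSE] %*%
                    diag(s$d[seq_len(k)], k), 2, flip, "*")
  loadings <- sweep(s$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  list(scores = scores, loadings = loadings,
       explained_variance = s$d^2 / sum(s$d^2))
}

#' Flag outlying samples on PCA scores
#'
#' Robust squared distance on the first two components (median-centred,
#' MAD-scaled per axis) compared against a chi-squared quantile. Samples
#' are flagged, never removed; re-processing without them is a pipeline
#' option, not an automatic step.
#'
#' @param scores score matrix from [pca_scores()] (>= 2 columns).
#' @param quantile chi-squared quantile defining the boundary
#'   (default 0.975).
#' @return data.frame: `sample`, `distance2`, `flagged`.
#' @export
outlier_flag <- function(scores, quantile = 0.975) {
  stopifnot(ncol(scores) >= 2)
  z <- scale(scores[, 1:2],
             center = apply(scores[, 1:2], 2, stats::median),
             scale = apply(scores[, 1:2], 2, stats::mad))
  d2 <- rowSums(z^2)
  data.frame(
    sample = if (is.null(rownames(scores))) seq_len(nrow(scores))
             else rownames(scores),
    distance2 = d2,
    flagged = d2 > stats::qchisq(quantile, df = 2),
    stringsAsFactors = FALSE
  )
}

#' Per-feature one-way ANOVA with FDR correction
#'
#' Vectorised one-way ANOVA of every feature over a sample grouping,
#' using only non-missing values (the tests are meant to run on
#' non-imputed data). P-values are adjusted across features
#' (Benjamini-Hochberg by default); the significant set is
#' `adjusted_p <= alpha`. Features for which fewer than two groups retain
#' any values are skipped (NA p-values, counted in the `skipped`
#' attribute).
#'
#' @param fm a [feature_matrix()] or numeric samples x features matrix.
#' @param groups grouping vector (length = samples) or the name of a
#'   sample-metadata column.
#' @param alpha significance level (default 0.05).
#' @param fdr_method method for [stats::p.adjust()] (default `"BH"`).
#' @return data.frame of class `anova_results`: `feature_id`, `raw_p`,
#'   `adjusted_p`, `significant`, plus per-group mean columns; attribute
#'   `n_significant`.
#' @export
anova_fdr <- function(fm, groups, alpha = 0.05, fdr_method = "BH") {
  is_fm <- inherits(fm, "feature_matrix")
  v <- if (is_fm) fm$values else as.matrix(fm)
  if (is.character(groups) && length(groups) == 1 && is_fm) {
    if (!groups %in% names(fm$samples)) {
      stop("no sample column '", groups, "'", call. = FALSE)
    }
    groups <- fm$samples[[groups]]
  }
  f <- factor(groups)
  stopifnot(length(f) == nrow(v), nlevels(f) >= 2, alpha > 0, alpha < 1)
  lev <- levels(f)
  obs <- !is.na(v)
  vz <- v; vz[!obs] <- 0
  ng <- rowsum(obs * 1, f)                    # groups x features counts
  sg <- rowsum(vz, f)                         # group sums
  ssg <- rowsum(vz^2, f)
  n_tot <- colSums(ng)
  k_eff <- colSums(ng > 0)
  mg <- sg / ng                               # NaN where group absent
  grand <- colSums(sg) / n_tot
  ssb <- colSums(ng * sweep(mg, 2, grand)^2, na.rm = TRUE)
  ssw <- colSums(ssg - sg^2 / ifelse(ng > 0, ng, 1) * (ng > 0))
  df1 <- k_eff - 1
  df2 <- n_tot - k_eff
  sst <- ssb + ssw
  tol <- 1e-12 * pmax(sst, colSums(ssg))
  p <- rep(NA_real_, ncol(v))
  testable <- k_eff >= 2 & df2 >= 1
  const <- testable & sst <= tol              # all values identical
  p[const] <- 1
  run <- testable & !const
  fstat <- (ssb[run] / df1[run]) / pmax(ssw[run] / df2[run], .Machine$double.xmin)
  p[run] <- stats::pf(fstat, df1[run], df2[run], lower.tail = FALSE)
  adj <- rep(NA_real_, length(p))
  adj[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = fdr_method)
  res <- data.frame(
    feature_id = if (is_fm) fm$features$feature_id else
      (if (is.null(colnames(v))) sprintf("F%05d", seq_len(ncol(v)))
       else colnames(v)),
    raw_p = p, adjusted_p = adj,
    significant = !is.na(adj) & adj <= alpha,
    stringsAsFactors = FALSE
  )
  for (g in lev) res[[paste0("mean_", g)]] <- mg[g, ]
  class(res) <- c("anova_results", class(res))
  attr(res, "n_significant") <- sum(res$significant)
  attr(res, "skipped") <- sum(!testable)
  attr(res, "alpha") <- alpha
  res
}

#' Tukey-Kramer post-hoc pairwise comparisons
#'
#' Studentised-range-based pairwise tests with the Tukey-Kramer
#' unequal-n standard error, `se_ij = sqrt(MSE/2 * (1/n_i + 1/n_j))`,
#' reducing to the classical Tukey HSD for balanced groups. Groups with
#' fewer than two values are excluded.
#'
#' @param values numeric response vector.
#' @param groups grouping vector of the same length.
#' @return data.frame: `group1`, `group2`, `diff` (mean difference),
#'   `se`, `q` (studentised range statistic), `p_adj`.
#' @export
tukey_kramer <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  f <- factor(as.character(groups[ok]))
  n <- tapply(values, f, length)
  small <- names(n)[n < 2]
  if (length(small)) {
    message("group(s) with < 2 values excluded from post-hoc pairs: ",
            paste(small, collapse = ", "))
    keep <- !(f %in% small)
    values <- values[keep]
    f <- droplevels(f[keep])
    n <- tapply(values, f, length)
  }
  k <- nlevels(f)
  if (k < 2) stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  m <- tapply(values, f, mean)
  df <- length(values) - k
  mse <- sum(tapply(values, f, function(x) sum((x - mean(x))^2))) / df
  pairs <- utils::combn(levels(f), 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    stringsAsFactors = FALSE)
  out$diff <- as.vector(m[out$group2] - m[out$group1])
  out$se <- as.vector(sqrt(mse / 2 * (1 / n[out$group1] + 1 / n[out$group2])))
  out$q <- abs(out$diff) / out$se
  out$p_adj <- if (mse <= 0) as.numeric(out$q == 0) else
    stats::ptukey(out$q, nmeans = k, df = df, lower.tail = FALSE)
  rownames(out) <- NULL
  out
}

#' Rate of significant change per hour between consecutive time points
#'
#' Normalises the count of significantly changing features between each
#' pair of consecutive sampling times by the length of the interval, so
#' unevenly spaced time courses (e.g. 1, 2, 6, 24, 48 h) are comparable.
#'
#' @param counts significant-feature counts, one per consecutive
#'   interval.
#' @param time_points strictly increasing sampling times in hours
#'   (length `length(counts) + 1`).
#' @return data.frame: `from_h`, `to_h`, `n_significant`,
#'   `rate_per_hour`.
#' @export
per_hour_change_rate <- function(counts, time_points) {
  if (anyDuplicated(time_points) || is.unsorted(time_points, strictly = TRUE)) {
    stop("time points must be strictly increasing and unique", call. = FALSE)
  }
  if (length(counts) != length(time_points) - 1) {
    stop("need one count per consecutive pair of time points", call. = FALSE)
  }
  data.frame(
    from_h = time_points[-length(time_points)],
    to_h = time_points[-1],
    n_significant = counts,
    rate_per_hour = counts / diff(time_points)
  )
}

#' Features significant at every time point
#'
#' @param results list of `anova_results` (one per time point).
#' @param alpha significance level applied to adjusted p-values.
#' @return character vector of feature ids in the intersection.
#' @export
significant_at_all_times <- function(results, alpha = 0.05) {
  sets <- lapply(results, function(r) {
    r$feature_id[!is.na(r$adjusted_p) & r$adjusted_p <= alpha]
  })
  Reduce(intersect, sets)
}
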