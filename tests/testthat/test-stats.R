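complete_fm <- function(vals, classes = NULL) {
  n <- nrow(vals)
  feature_matrix(vals,
                 data.frame(feature_id = sprintf("f%03d", seq_len(ncol(vals))),
                            mz = 100 + seq_len(ncol(vals))),
                 data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                            class = classes %||% rep("sample", n)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("KNN imputation: identity on complete data, exact on a twin feature", {
  set.seed(1)
  vals <- matrix(rlnorm(5 * 4, log(10), 0.3), nrow = 5)
  fm <- complete_fm(vals)
  expect_identical(impute_knn(fm, 5)$values, fm$values)
  # two perfectly correlated features, k = 1: imputed from the twin exactly
  twin <- cbind(c(1, 2, 3, 4, 5), c(1, 2, 3, NA, 5), runif(5, 10, 20))
  out <- impute_knn(twin, k = 1)
  expect_equal(out[4, 2], twin[4, 1])
  # observed entries are untouched
  expect_identical(out[-4, 2], twin[-4, 2])
  expect_error(impute_knn(cbind(c(NA, NA), c(1, 2))), "no observed values")
})

test_that("KNN imputation recovers MCAR dropout with small relative error", {
  met <- grid_metabolites(120, 51, 590)
  cfg <- acquisition_config(window_ranges = cbind(50, 600),
                            technical_cv = 0.1, peak_dropout_prob = 0,
                            mz_jitter_ppm = 0, seed = 61)
  fm <- truth_matrix(simulate_plate(plate_layout(n_samples = 20), met, cfg))
  truth <- fm$values
  set.seed(62)
  holes <- sample(length(truth), round(0.05 * length(truth)))
  fm$values[holes] <- NA
  imp <- impute_knn(fm, k = 5)
  rel_err <- abs(imp$values[holes] - truth[holes]) / truth[holes]
  expect_lt(median(rel_err), 0.15)
})

test_that("glog reduces to ln at lambda 0 and is monotone for any lambda", {
  x <- matrix(c(0.5, 1, 10, 1e4), nrow = 1)
  expect_equal(glog_transform(x, lambda = 0), log(x), ignore_attr = TRUE)
  for (lam in c(0, 1, 1e4)) {
    xs <- sort(runif(50, 0, 1e3))
    g <- glog_transform(matrix(xs, nrow = 1), lambda = lam)
    expect_true(all(diff(as.numeric(g)) > 0))
  }
  expect_error(glog_transform(x, lambda = -1), ">= 0")
})

test_that("glog with QC-estimated lambda stabilises variance across intensity strata", {
  set.seed(71)
  n <- 40
  mu <- c(rep(100, 50), rep(1e5, 50))           # low and high strata
  vals <- t(replicate(n, mu * rlnorm(100, -log(1.01) / 2, sqrt(log(1.01)))))
  fm <- complete_fm(vals, classes = rep(c("QC", "sample"), each = n / 2))
  raw_ratio <- median(apply(vals[, 51:100], 2, var)) /
    median(apply(vals[, 1:50], 2, var))
  expect_gt(raw_ratio, 10)
  g <- glog_transform(fm)
  g_ratio <- median(apply(g$values[, 51:100], 2, var)) /
    median(apply(g$values[, 1:50], 2, var))
  expect_gt(g_ratio, 0.5)
  expect_lt(g_ratio, 2)
})

test_that("PCA matches the SVD oracle and fixes component signs", {
  set.seed(81)
  for (i in 1:5) {
    x <- matrix(rnorm(20 * 50), nrow = 20)
    p <- pca_scores(x, n_components = 5)
    xc <- sweep(x, 2, colMeans(x))
    s <- svd(xc)
    for (k in 1:5) {
      expect_equal(abs(p$scores[, k]), abs(s$u[, k] * s$d[k]), tolerance = 1e-8)
      # sign convention: dominant loading positive
      expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
    }
    expect_true(all(diff(p$explained_variance) <= 1e-12))
  }
  # data on one axis: PC1 explains everything
  one_axis <- cbind(rnorm(10), 0, 0)
  p1 <- pca_scores(one_axis, 2)
  expect_equal(p1$explained_variance[1], 1)
  expect_error(pca_scores(one_axis[1, , drop = FALSE]), "at least 2 samples")
})

test_that("a planted class shift separates groups in PCA score space", {
  hits <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    vals <- matrix(rlnorm(16 * 200, log(1e4), 0.3), nrow = 16)
    vals[9:16, 1:20] <- vals[9:16, 1:20] * 2
    p <- pca_scores(glog_transform(vals, lambda = 0), 2)
    cl <- rep(1:2, each = 8)
    # positive silhouette on the first two PCs
    d <- as.matrix(dist(p$scores))
    sil <- vapply(1:16, function(i) {
      a <- mean(d[i, cl == cl[i]][-which(which(cl == cl[i]) == i)])
      b <- mean(d[i, cl != cl[i]])
      (b - a) / max(a, b)
    }, numeric(1))
    mean(sil) > 0
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("robust outlier flagging catches extremes at the expected rate", {
  set.seed(91)
  scores <- matrix(rnorm(2000 * 2), ncol = 2)
  fl <- outlier_flag(scores)
  expect_gt(mean(fl$flagged), 0.01)
  expect_lt(mean(fl$flagged), 0.055)
  scores[1, 1] <- 10 * sd(scores[, 1])
  expect_true(outlier_flag(scores)$flagged[1])
  # removing flags and re-flagging does not cascade toward empty
  keep <- scores[!fl$flagged, ]
  fl2 <- outlier_flag(keep)
  expect_lt(mean(fl2$flagged), 0.08)
})

test_that("vectorised ANOVA matches aov on data with missing values", {
  set.seed(101)
  vals <- matrix(rlnorm(20 * 30, log(100), 0.4), nrow = 20)
  vals[sample(length(vals), 40)] <- NA
  groups <- rep(c("a", "b", "c", "d"), each = 5)
  res <- anova_fdr(vals, groups)
  for (j in c(1, 7, 19, 30)) {
    ok <- !is.na(vals[, j])
    p_oracle <- summary(aov(vals[ok, j] ~ factor(groups[ok])))[[1]][1, "Pr(>F)"]
    expect_equal(res$raw_p[j], p_oracle, tolerance = 1e-10)
  }
  expect_equal(res$adjusted_p, p.adjust(res$raw_p, "BH"))
})

test_that("ANOVA handles constants, relabelling and rescaling", {
  vals <- matrix(5, nrow = 12, ncol = 4)
  res <- anova_fdr(vals, rep(1:3, each = 4))
  expect_identical(attr(res, "n_significant"), 0L)
  expect_true(all(res$raw_p == 1))
  set.seed(111)
  vals2 <- matrix(rlnorm(12 * 20), nrow = 12)
  g <- rep(c("x", "y", "z"), each = 4)
  r1 <- anova_fdr(vals2, g)
  # relabel samples within groups
  perm <- c(sample(1:4), sample(5:8), sample(9:12))
  r2 <- anova_fdr(vals2[perm, ], g[perm])
  expect_equal(r1$raw_p, r2$raw_p, tolerance = 1e-12)
  r3 <- anova_fdr(vals2 * 1e6, g)
  expect_equal(r1$raw_p, r3$raw_p, tolerance = 1e-9)
  # BH adjustment is monotone in raw-p rank
  o <- order(r1$raw_p)
  expect_true(all(diff(r1$adjusted_p[o]) >= -1e-15))
})

test_that("features with a fully missing group are tested on the remaining groups", {
  vals <- matrix(rlnorm(12 * 2), nrow = 12)
  vals[1:4, 1] <- NA                       # group "a" absent for feature 1
  vals[c(1:4, 5:8), 2] <- NA               # only one group left for feature 2
  res <- anova_fdr(vals, rep(c("a", "b", "c"), each = 4))
  ok <- !is.na(vals[, 1])
  p_oracle <- summary(aov(vals[ok, 1] ~ factor(rep(c("b", "c"), each = 4))))[[1]][1, "Pr(>F)"]
  expect_equal(res$raw_p[1], p_oracle, tolerance = 1e-10)
  expect_true(is.na(res$raw_p[2]))
  expect_identical(attr(res, "skipped"), 1L)
})

test_that("null simulations keep the BH false-discovery fraction at bay", {
  fracs <- vapply(1:50, function(s) {
    set.seed(2000 + s)
    d <- lognormal_matrix(8, 5, 400, cv = 0.1)
    res <- anova_fdr(d$values, d$groups)
    mean(res$significant)
  }, numeric(1))
  mc_se <- sd(fracs) / sqrt(length(fracs))
  expect_lte(mean(fracs), 0.05 + 3 * mc_se)
})

test_that("planted three-fold effects are detected with high power", {
  detected <- vapply(1:10, function(s) {
    set.seed(3000 + s)
    d <- lognormal_matrix(8, 5, 300, cv = 0.1)
    d$values[d$groups == "g5", 1:30] <- d$values[d$groups == "g5", 1:30] * 3
    res <- anova_fdr(d$values, d$groups)
    sum(res$significant[1:30])
  }, numeric(1))
  expect_gte(median(detected), 27)  # >= 90% of the planted features
  # power is non-decreasing in fold change
  power_at <- vapply(c(1.2, 2, 3), function(fold) {
    set.seed(42)
    d <- lognormal_matrix(8, 5, 300, cv = 0.1)
    d$values[d$groups == "g5", 1:30] <- d$values[d$groups == "g5", 1:30] * fold
    sum(anova_fdr(d$values, d$groups)$significant[1:30])
  }, numeric(1))
  expect_true(all(diff(power_at) >= 0))
})

test_that("Tukey-Kramer agrees with the aov-based oracle on unbalanced groups", {
  set.seed(121)
  values <- c(rnorm(4, 10), rnorm(7, 11), rnorm(5, 13))
  groups <- rep(c("a", "b", "c"), c(4, 7, 5))
  got <- tukey_kramer(values, groups)
  want <- TukeyHSD(aov(values ~ factor(groups)))$`factor(groups)`
  # TukeyHSD labels pairs "b-a", "c-a", "c-b"
  key <- paste0(got$group2, "-", got$group1)
  expect_equal(got$p_adj, unname(want[key, "p adj"]), tolerance = 1e-6)
  expect_equal(got$diff, unname(want[key, "diff"]), tolerance = 1e-9)
  # balanced case reduces to the classical Tukey HSD
  vb <- rnorm(15); gb <- rep(c("a", "b", "c"), each = 5)
  got_b <- tukey_kramer(vb, gb)
  want_b <- TukeyHSD(aov(vb ~ factor(gb)))$`factor(gb)`
  expect_equal(got_b$p_adj,
               unname(want_b[paste0(got_b$group2, "-", got_b$group1), "p adj"]),
               tolerance = 1e-6)
})

test_that("Tukey-Kramer degenerate cases: identical groups, tiny groups", {
  got <- tukey_kramer(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_gt(got$p_adj, 0.99)
  expect_message(
    got2 <- tukey_kramer(c(1, 2, 3, 4, 9), rep(c("a", "b", "c"), c(2, 2, 1))),
    "excluded")
  expect_identical(nrow(got2), 1L)
  expect_error(tukey_kramer(c(1, 2), c("a", "b")), ">= 2 groups")
})

test_that("per-hour change rates normalise by interval length", {
  r <- per_hour_change_rate(120, c(24, 48))
  expect_equal(r$rate_per_hour, 5.0)
  expect_equal(per_hour_change_rate(0, c(1, 2))$rate_per_hour, 0)
  # the 1, 2, 6, 24, 48 h design yields divisors 1, 4, 18, 24
  r5 <- per_hour_change_rate(c(10, 40, 180, 240), c(1, 2, 6, 24, 48))
  expect_equal(r5$to_h - r5$from_h, c(1, 4, 18, 24))
  expect_equal(r5$rate_per_hour, c(10, 10, 10, 10))
  expect_error(per_hour_change_rate(c(1, 2), c(1, 1, 6)), "strictly increasing")
  expect_error(per_hour_change_rate(c(1), c(1, 6, 24)), "one count per")
})

test_that("the all-time-points intersection uses strict set semantics", {
  mk <- function(sig) {
    data.frame(feature_id = c("f1", "f2", "f3"),
               adjusted_p = ifelse(c("f1", "f2", "f3") %in% sig, 0.01, 0.5))
  }
  res <- list(mk(c("f1", "f2")), mk(c("f1", "f2")), mk("f1"))
  expect_identical(significant_at_all_times(res), "f1")
  res2 <- list(mk(c("f1")), mk(character(0)))
  expect_length(significant_at_all_times(res2), 0)
  # features recovered exactly when the effect dwarfs the noise
  set.seed(131)
  results <- lapply(1:3, function(t) {
    d <- lognormal_matrix(6, 2, 50, cv = 0.05)
    d$values[d$groups == "g2", 1:5] <- d$values[d$groups == "g2", 1:5] * 10
    anova_fdr(d$values, d$groups)
  })
  expect_setequal(significant_at_all_times(results),
                  sprintf("F%05d", 1:5))
})
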