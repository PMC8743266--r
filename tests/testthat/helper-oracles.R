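# Independent oracles and small fixture builders shared across tests.

# brute-force single-linkage clustering of m/z at a ppm cut, on the same
# log-m/z metric the package documents, via hclust (independent of
# cluster_mz's gap-splitting implementation)
oracle_single_linkage <- function(mz, ppm) {
  if (length(mz) == 1) return(1L)
  u <- 1e6 * log(mz)
  hc <- hclust(dist(u), method = "single")
  cl <- cutree(hc, h = ppm)
  # renumber in ascending m/z order for comparability
  first <- tapply(mz, cl, min)
  match(cl, as.integer(names(sort(first))))
}

# all-pairs accurate-mass annotation scan
oracle_annotate <- function(mz, compounds, rules, tol_ppm) {
  hits <- list()
  for (i in seq_along(mz)) {
    for (c in seq_len(nrow(compounds))) {
      for (r in seq_len(nrow(rules))) {
        theo <- rules$multiplicity[r] * compounds$monoisotopic_mass[c] +
          rules$mass_shift[r]
        if (theo > 0 && abs(1e6 * (mz[i] - theo) / theo) <= tol_ppm) {
          hits[[length(hits) + 1]] <- data.frame(
            feature = i, compound_id = compounds$id[c],
            adduct = rules$name[r], theoretical_mz = theo,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) return(NULL)
  out <- do.call(rbind, hits)
  out[order(out$feature, out$compound_id, out$adduct), ]
}

# grid metabolite table (no randomness, exact spacing) for targeted tests
grid_metabolites <- function(n, mz_from = 60, mz_to = 140,
                             base_intensity = 1e5, adducts = "[M-H]-",
                             contaminants = 0L) {
  shift <- adduct_rules()$mass_shift[match(strsplit(adducts, ";")[[1]][1],
                                           adduct_rules()$name)]
  mz <- seq(mz_from, mz_to, length.out = n)
  data.frame(
    id = sprintf("G%04d", seq_len(n)),
    monoisotopic_mass = mz - shift,
    base_intensity = rep_len(base_intensity, n),
    adducts = adducts,
    is_contaminant = rep(c(FALSE, TRUE), c(n - contaminants, contaminants)),
    stringsAsFactors = FALSE
  )
}

# two-window configuration used by several tests
two_window_config <- function(...) {
  acquisition_config(window_ranges = cbind(c(50, 140), c(150, 250)), ...)
}

noise_free <- function(config) {
  config$technical_cv <- 0
  config$peak_dropout_prob <- 0
  config$mz_jitter_ppm <- 0
  config$drift_model <- "none"
  config
}

# direct lognormal samples x features matrix for statistical tests
lognormal_matrix <- function(n_per_group, n_groups, n_features, cv,
                             group_prefix = "g") {
  s2 <- log(1 + cv^2)
  n <- n_per_group * n_groups
  m <- matrix(rlnorm(n * n_features, log(1e5) - s2 / 2, sqrt(s2)),
              nrow = n, ncol = n_features)
  list(values = m,
       groups = rep(paste0(group_prefix, seq_len(n_groups)),
                    each = n_per_group))
}
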