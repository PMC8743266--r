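# End-to-end orchestration: simulate -> write/read peak lists ->
# process -> normalise/QC -> statistics -> annotation, with every
# artefact written as TSV. Deterministic per configuration seed.

#' Count significantly changing features between consecutive time points
#'
#' For each consecutive pair of sampling times, runs a per-feature
#' one-way test between the two time groups (FDR-corrected across
#' features) on the requested class and converts counts to per-hour
#' rates.
#'
#' @param fm a [feature_matrix()] whose samples carry `time_h`.
#' @param class sample class analysed (default `"sample"`).
#' @param alpha significance level on adjusted p-values.
#' @param fdr_method FDR method for [anova_fdr()].
#' @return list: `rates` (see [per_hour_change_rate()]) and `results`
#'   (per-interval `anova_results`).
#' @export
consecutive_time_changes <- function(fm, class = "sample", alpha = 0.05,
                                     fdr_method = "BH") {
  idx <- which(fm$samples$class == class & !is.na(fm$samples$time_h))
  times <- sort(unique(fm$samples$time_h[idx]))
  if (length(times) < 2) stop("need >= 2 time points", call. = FALSE)
  results <- vector("list", length(times) - 1)
  counts <- integer(length(times) - 1)
  for (i in seq_len(length(times) - 1)) {
    pair <- idx[fm$samples$time_h[idx] %in% times[c(i, i + 1)]]
    sub <- fm_subset(fm, samples = pair)
    res <- anova_fdr(sub, groups = factor(sub$samples$time_h),
                     alpha = alpha, fdr_method = fdr_method)
    results[[i]] <- res
    counts[i] <- attr(res, "n_significant")
  }
  list(rates = per_hour_change_rate(counts, times), results = results)
}

#' Run the complete workflow on a simulated plate
#'
#' Simulates acquisitions, writes and re-reads the peak lists (the
#' on-disk path is exercised, not bypassed), processes them into a
#' feature matrix, applies PQN, optional drift correction and the QC-RSD
#' filter, produces repeatability reports, PCA and per-time-point ANOVA
#' summaries, and (given a compound table) accurate-mass annotations.
#' All outputs are TSV files under `out_dir`; identical seeds give
#' byte-identical directories.
#'
#' @param out_dir output directory.
#' @param layout plate layout (see [plate_layout()]).
#' @param metabolites metabolite library.
#' @param config an [acquisition_config()].
#' @param params a [process_params()].
#' @param effects optional planted effects (see [plant_effects()]).
#' @param compounds optional compound table for annotation.
#' @param mode ionisation mode for annotation.
#' @param drift_correction apply QC-anchored drift correction when
#'   enough QCs are present (default: only when the configuration
#'   simulates drift).
#' @param alpha significance level for the statistics stage.
#' @param overwrite replace existing outputs?
#' @return invisibly, a list with the main in-memory results (`fm_final`,
#'   `qc_report`, `pca`, `anova`, `annotations`, `stage_log`).
#' @export
run_study <- function(out_dir, layout, metabolites, config,
                      params = process_params(), effects = NULL,
                      compounds = NULL, mode = "negative",
                      drift_correction = NULL, alpha = 0.05,
                      overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_plate(layout, metabolites, config, effects)
  write_peaklists(sim$scans, file.path(out_dir, "peaklists"),
                  overwrite = overwrite)
  write_ground_truth(sim$truth, file.path(out_dir, "ground_truth.tsv"),
                     overwrite = overwrite)
  .write_tsv(sim$layout, file.path(out_dir, "samples.tsv"))

  scans <- read_peaklists(file.path(out_dir, "peaklists"))
  proc <- process_plate(scans, sim$layout, config$window_ranges, params)
  write_feature_matrix(proc$fm, file.path(out_dir, "matrix_raw"),
                       overwrite = overwrite)
  if (!is.null(proc$blank_report)) {
    .write_tsv(proc$blank_report, file.path(out_dir, "blank_removals.tsv"))
  }

  pq <- pqn_normalize(proc$fm)
  fm <- pq$fm
  .write_tsv(data.frame(sample_id = names(pq$factors),
                        pqn_factor = unname(pq$factors)),
             file.path(out_dir, "pqn_factors.tsv"))
  has_qc <- sum(fm$samples$class == "QC") >= 4
  if (is.null(drift_correction)) {
    drift_correction <- config$drift_model != "none" && has_qc
  }
  if (drift_correction && has_qc) fm <- drift_correct(fm)
  if (sum(fm$samples$class == "QC") >= 2) fm <- qc_rsd_filter(fm)
  write_feature_matrix(fm, file.path(out_dir, "matrix_final"),
                       overwrite = overwrite)

  qc_rep <- tryCatch(assess_repeatability(fm, "qc"), error = function(e) NULL)
  if (!is.null(qc_rep)) {
    write_qc_report(qc_rep, file.path(out_dir, "qc_report.tsv"),
                    overwrite = overwrite)
  }

  # statistics: PCA on imputed + glog + mean-centred data, tests on
  # non-imputed intensities
  si <- which(fm$samples$class == "sample")
  pca <- anova <- NULL
  if (length(si) >= 3) {
    sub <- fm_subset(fm, samples = si)
    sub <- sample_presence_filter(sub, 0.5)  # guard: impute needs >=1 obs
    imp <- impute_knn(sub, k = 5)
    gl <- glog_transform(imp, qc_class = "QC")
    pca <- pca_scores(gl, n_components = min(5, length(si) - 1))
    sc <- as.data.frame(pca$scores)
    sc <- cbind(sample_id = sub$samples$sample_id, sc)
    .write_tsv(sc, file.path(out_dir, "pca_scores.tsv"))
    .write_tsv(outlier_flag(pca$scores), file.path(out_dir, "outlier_flags.tsv"))
    grp <- if (length(unique(sub$samples$exposure)) >= 2) "exposure" else
      if (length(unique(sub$samples$time_h)) >= 2) "time_h" else NULL
    if (!is.null(grp)) {
      anova <- anova_fdr(sub, grp, alpha = alpha)
      .write_tsv(as.data.frame(anova), file.path(out_dir, "anova_results.tsv"))
    }
  }

  annotations <- NULL
  if (!is.null(compounds)) {
    annotations <- annotate_features(fm, compounds, mode = mode)
    write_annotations(as.data.frame(annotations),
                      file.path(out_dir, "annotations.tsv"),
                      overwrite = overwrite)
  }
  log_df <- data.frame(stage = names(proc$stage_log),
                       count = unname(proc$stage_log))
  log_df <- rbind(log_df,
                  data.frame(stage = "final_features", count = ncol(fm$values)))
  .write_tsv(log_df, file.path(out_dir, "stage_log.tsv"))
  invisible(list(fm_final = fm, qc_report = qc_rep, pca = pca, anova = anova,
                 annotations = annotations, stage_log = proc$stage_log,
                 simulation = sim))
}
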