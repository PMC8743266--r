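# On-disk formats. Everything is plain TSV for diffability: one peak-list
# file per sample (sections implied by window/replicate columns), a
# three-file feature-matrix directory, and single-table TSVs for ground
# truth, QC reports, annotations and compound databases. Missing values
# are serialised as empty fields, never 0 or a sentinel.

.write_tsv <- function(df, path, header_lines = character(0)) {
  out <- df
  for (j in seq_along(out)) {
    col <- out[[j]]
    s <- if (is.double(col)) {
      format(col, digits = 12, trim = TRUE, scientific = FALSE)
    } else {
      as.character(col)
    }
    s[is.na(col)] <- ""
    out[[j]] <- s
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path, colClasses = NA) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = "", colClasses = colClasses)
}

.check_overwrite <- function(path, overwrite) {
  if (file.exists(path) && !overwrite) {
    stop("'", path, "' exists; pass overwrite = TRUE to replace it",
         call. = FALSE)
  }
}

#' Write per-sample peak-list files
#'
#' One TSV per sample (`<sample_id>.peaklist.tsv`) with columns
#' `window_index`, `replicate_index`, `mz`, `intensity`, `snr`, sorted by
#' window, replicate and m/z. m/z is written with full double precision.
#'
#' @param scans long peak table as produced by [simulate_plate()] (or its
#'   reader round trip), with a `sample_id` column.
#' @param dir output directory (created if needed).
#' @param overwrite replace existing files?
#' @return invisibly, the paths written.
#' @export
write_peaklists <- function(scans, dir, overwrite = FALSE) {
  need <- c("sample_id", "window_index", "replicate_index", "mz", "intensity")
  stopifnot(all(need %in% names(scans)))
  if (!"snr" %in% names(scans)) scans$snr <- NA_real_
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sid in unique(scans$sample_id)) {
    path <- file.path(dir, paste0(sid, ".peaklist.tsv"))
    .check_overwrite(path, overwrite)
    s <- scans[scans$sample_id == sid,
               c("window_index", "replicate_index", "mz", "intensity", "snr")]
    s <- s[order(s$window_index, s$replicate_index, s$mz), ]
    .write_tsv(s, path, header_lines = c(paste0("sample_id=", sid),
                                         "format=stitchdims-peaklist-v1"))
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a directory of peak-list files
#'
#' Validates every record: positive intensities, integer window/replicate
#' indices, no duplicated (window, replicate) section out of m/z order
#' (unsorted sections are sorted with a warning), no duplicate files per
#' sample.
#'
#' @param dir directory of `*.peaklist.tsv` files.
#' @return long peak table (`sample_id`, `window_index`,
#'   `replicate_index`, `mz`, `intensity`, `snr`).
#' @export
read_peaklists <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.peaklist\\.tsv$",
                           full.names = TRUE))
  if (!length(files)) stop("no *.peaklist.tsv files in '", dir, "'", call. = FALSE)
  out <- vector("list", length(files))
  seen <- character(0)
  for (i in seq_along(files)) {
    f <- files[i]
    hdr <- readLines(f, n = 5L)
    sid <- sub("^# sample_id=", "", grep("^# sample_id=", hdr, value = TRUE))
    if (length(sid) != 1) {
      stop("file '", f, "': missing '# sample_id=' header line", call. = FALSE)
    }
    if (sid %in% seen) stop("duplicate sample_id '", sid, "'", call. = FALSE)
    seen <- c(seen, sid)
    df <- .read_tsv(f)
    need <- c("window_index", "replicate_index", "mz", "intensity")
    if (!all(need %in% names(df))) {
      stop("file '", f, "': missing column(s) ",
           paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
    }
    if (!"snr" %in% names(df)) df$snr <- NA_real_
    n_hdr <- sum(startsWith(hdr, "#")) + 1L  # comment lines + column header
    bad <- which(!is.finite(df$intensity) | df$intensity <= 0)
    if (length(bad)) {
      stop("file '", f, "', line ", bad[1] + n_hdr,
           ": intensity must be > 0 (got ", df$intensity[bad[1]], ")",
           call. = FALSE)
    }
    bad <- which(is.na(df$mz) | df$mz <= 0)
    if (length(bad)) {
      stop("file '", f, "', line ", bad[1] + n_hdr,
           ": m/z must be > 0", call. = FALSE)
    }
    key <- paste(df$window_index, df$replicate_index)
    resorted <- FALSE
    for (k in unique(key)) {
      idx <- which(key == k)
      if (is.unsorted(df$mz[idx])) resorted <- TRUE
    }
    if (resorted) {
      warning("file '", f, "': peaks not sorted by m/z; sorting", call. = FALSE)
    }
    df <- df[order(df$window_index, df$replicate_index, df$mz), ]
    df$sample_id <- sid
    out[[i]] <- df[c("sample_id", "window_index", "replicate_index",
                     "mz", "intensity", "snr")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a feature matrix as a three-file TSV directory
#'
#' Writes `features.tsv`, `samples.tsv` and `values.tsv` (samples in rows,
#' feature ids as columns, missing cells empty). m/z is serialised with
#' full double precision; round trips are lossless to ~1e-12 relative.
#'
#' @param fm a [feature_matrix()].
#' @param dir output directory.
#' @param overwrite replace existing files?
#' @return invisibly, `dir`.
#' @export
write_feature_matrix <- function(fm, dir, overwrite = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in c("features.tsv", "samples.tsv", "values.tsv")) {
    .check_overwrite(file.path(dir, f), overwrite)
  }
  .write_tsv(fm$features, file.path(dir, "features.tsv"))
  .write_tsv(fm$samples, file.path(dir, "samples.tsv"))
  vals <- as.data.frame(fm$values, check.names = FALSE)
  vals <- cbind(sample_id = fm$samples$sample_id, vals)
  .write_tsv(vals, file.path(dir, "values.tsv"))
  invisible(dir)
}

#' Read a feature-matrix directory written by [write_feature_matrix()]
#'
#' @param dir directory holding `features.tsv`, `samples.tsv`,
#'   `values.tsv`.
#' @return a [feature_matrix()].
#' @export
read_feature_matrix <- function(dir) {
  features <- .read_tsv(file.path(dir, "features.tsv"))
  samples <- .read_tsv(file.path(dir, "samples.tsv"))
  vals <- .read_tsv(file.path(dir, "values.tsv"))
  if (names(vals)[1] != "sample_id") {
    stop("values.tsv must start with a sample_id column", call. = FALSE)
  }
  m <- as.matrix(vals[, -1, drop = FALSE])
  # TSV column names pass through make.names; restore from features.tsv
  if (ncol(m) != nrow(features)) {
    stop("values.tsv has ", ncol(m), " feature columns but features.tsv has ",
         nrow(features), " rows", call. = FALSE)
  }
  colnames(m) <- features$feature_id
  if (!identical(as.character(vals$sample_id), as.character(samples$sample_id))) {
    stop("sample order in values.tsv does not match samples.tsv", call. = FALSE)
  }
  feature_matrix(m, features, samples)
}

#' Write / read the simulator ground-truth table
#'
#' @param truth ground-truth data.frame from [simulate_plate()].
#' @param path TSV path.
#' @param overwrite replace an existing file?
#' @return `write_ground_truth` invisibly returns `path`;
#'   `read_ground_truth` returns the data.frame.
#' @export
write_ground_truth <- function(truth, path, overwrite = FALSE) {
  .check_overwrite(path, overwrite)
  .write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) .read_tsv(path)

#' Read a compound database table
#'
#' TSV with columns `id`, `name` and at least one of `formula`,
#' `monoisotopic_mass`. Missing masses are computed from the formula with
#' the bundled atomic mass table.
#'
#' @param path TSV path.
#' @return data.frame with `id`, `name`, `formula`, `monoisotopic_mass`.
#' @export
read_compound_table <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("id", "name") %in% names(df))) {
    stop("compound table needs columns id and name", call. = FALSE)
  }
  if (!"formula" %in% names(df)) df$formula <- NA_character_
  if (!"monoisotopic_mass" %in% names(df)) df$monoisotopic_mass <- NA_real_
  fill <- is.na(df$monoisotopic_mass)
  if (any(fill & is.na(df$formula))) {
    stop("compound(s) without formula or monoisotopic_mass: ",
         paste(utils::head(df$id[fill & is.na(df$formula)], 5), collapse = ", "),
         call. = FALSE)
  }
  df$monoisotopic_mass[fill] <- formula_mass(df$formula[fill])
  df
}

#' Write an annotation table
#'
#' @param ann annotation data.frame from [annotate_features()].
#' @param path TSV path.
#' @param overwrite replace an existing file?
#' @export
write_annotations <- function(ann, path, overwrite = FALSE) {
  .check_overwrite(path, overwrite)
  .write_tsv(ann, path)
  invisible(path)
}

#' Read simulator / processing parameters from YAML
#'
#' Recognised top-level keys: `acquisition` (arguments of
#' [acquisition_config()]) and `process` (arguments of
#' [process_params()]).
#'
#' @param path YAML file.
#' @return list with elements `acquisition` and/or `process`.
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(cfg$acquisition)) {
    a <- cfg$acquisition
    if (!is.null(a$window_ranges)) {
      a$window_ranges <- do.call(rbind, lapply(a$window_ranges, unlist))
    }
    out$acquisition <- do.call(acquisition_config, a)
  }
  if (!is.null(cfg$process)) out$process <- do.call(process_params, cfg$process)
  out
}
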