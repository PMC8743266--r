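# mzML ingestion (read-only, via mzR) plus a minimal mzML writer used to
# export simulated acquisitions, so ingestion can be exercised without
# instrument files. The writer emits uncompressed 64-bit little-endian
# arrays; it is a synthetic-data export, not a general-purpose converter.

#' Read a centroided mzML file into the peak-list representation
#'
#' Each spectrum is assigned a `(window_index, replicate_index)` via the
#' user-supplied window map: the recorded scan-window limits are matched
#' against the map (instrument scan-event naming is method-specific, so
#' the mapping is always explicit), and replicate indices count repeated
#' acquisitions of the same window in scan order.
#'
#' @param path mzML file.
#' @param window_map data.frame with `mz_low`, `mz_high`,
#'   `window_index`.
#' @param sample_id sample identifier to stamp on the peaks (default:
#'   file name without extension).
#' @param tol_da tolerance for matching scan-window limits (default
#'   0.5 Da).
#' @return long peak table (`sample_id`, `window_index`,
#'   `replicate_index`, `mz`, `intensity`, `snr` = `NA`).
#' @export
read_mzml <- function(path, window_map, sample_id = NULL, tol_da = 0.5) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("mzML ingestion requires the 'mzR' package", call. = FALSE)
  }
  stopifnot(all(c("mz_low", "mz_high", "window_index") %in% names(window_map)))
  if (is.null(sample_id)) {
    sample_id <- sub("\\.mzML$", "", basename(path), ignore.case = TRUE)
  }
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  hd <- mzR::header(ms)
  if ("centroided" %in% names(hd) && any(!is.na(hd$centroided) & !hd$centroided)) {
    stop("profile-mode spectra detected; centroid the data before ingestion",
         call. = FALSE)
  }
  lo <- if ("scanWindowLowerLimit" %in% names(hd)) hd$scanWindowLowerLimit
        else rep(NA_real_, nrow(hd))
  hi <- if ("scanWindowUpperLimit" %in% names(hd)) hd$scanWindowUpperLimit
        else rep(NA_real_, nrow(hd))
  miss <- is.na(lo) | is.na(hi)
  lo[miss] <- hd$lowMZ[miss]
  hi[miss] <- hd$highMZ[miss]
  win <- integer(nrow(hd))
  for (i in seq_len(nrow(hd))) {
    m <- which(abs(window_map$mz_low - lo[i]) <= tol_da &
                 abs(window_map$mz_high - hi[i]) <= tol_da)
    if (length(m) != 1) {
      m <- which(window_map$mz_low - tol_da <= lo[i] &
                   window_map$mz_high + tol_da >= hi[i])
    }
    if (length(m) != 1) {
      stop("spectrum ", i, " scan range [", format(lo[i]), ", ", format(hi[i]),
           "] does not map to exactly one SIM window; observed ranges: ",
           paste(sprintf("[%.1f, %.1f]", lo, hi), collapse = " "),
           call. = FALSE)
    }
    win[i] <- window_map$window_index[m]
  }
  rep_idx <- stats::ave(seq_len(nrow(hd)), win, FUN = seq_along)
  out <- vector("list", nrow(hd))
  for (i in seq_len(nrow(hd))) {
    pk <- mzR::peaks(ms, i)
    if (nrow(pk) == 0) next
    out[[i]] <- data.frame(
      sample_id = sample_id, window_index = win[i],
      replicate_index = rep_idx[i], mz = pk[, 1], intensity = pk[, 2],
      snr = NA_real_, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no peaks in '", path, "'", call. = FALSE)
  res <- res[order(res$window_index, res$replicate_index, res$mz), ]
  rownames(res) <- NULL
  res
}

.b64_doubles <- function(x) {
  # base64_enc wraps long output; mzML expects one unbroken token
  gsub("[\r\n ]", "", jsonlite::base64_enc(
    writeBin(as.numeric(x), raw(), size = 8, endian = "little")))
}

#' Export one sample's simulated scans as a minimal mzML file
#'
#' Writes one MS1 centroid spectrum per (window, scan replicate) with the
#' scan-window limits recorded, 64-bit uncompressed arrays. Intended for
#' testing mzML ingestion against the native peak-list path.
#'
#' @param scans peak rows of a single sample (long table with
#'   `window_index`, `replicate_index`, `mz`, `intensity`).
#' @param path output `.mzML` path.
#' @param window_ranges two-column matrix of SIM window ranges.
#' @param overwrite replace an existing file?
#' @return invisibly, `path`.
#' @export
write_mzml <- function(scans, path, window_ranges, overwrite = FALSE) {
  .check_overwrite(path, overwrite)
  stopifnot(length(unique(scans$sample_id)) <= 1)
  wins <- as.matrix(window_ranges)
  keys <- unique(scans[order(scans$window_index, scans$replicate_index),
                       c("window_index", "replicate_index")])
  spectra <- character(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    s <- scans[scans$window_index == keys$window_index[i] &
                 scans$replicate_index == keys$replicate_index[i], ]
    s <- s[order(s$mz), ]
    wi <- keys$window_index[i]
    mzb <- .b64_doubles(s$mz)
    inb <- .b64_doubles(s$intensity)
    spectra[i] <- paste0(
      '<spectrum index="', i - 1L, '" id="scan=', i, '" defaultArrayLength="',
      nrow(s), '">\n',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
      '<scanList count="1">\n',
      '<cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>\n',
      '<scan>\n<scanWindowList count="1">\n<scanWindow>\n',
      '<cvParam cvRef="MS" accession="MS:1000501" name="scan window lower limit" value="',
      format(wins[wi, 1], digits = 10), '" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
      '<cvParam cvRef="MS" accession="MS:1000500" name="scan window upper limit" value="',
      format(wins[wi, 2], digits = 10), '" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
      '</scanWindow>\n</scanWindowList>\n</scan>\n</scanList>\n',
      '<binaryDataArrayList count="2">\n',
      '<binaryDataArray encodedLength="', nchar(mzb), '">\n',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
      '<binary>', mzb, '</binary>\n</binaryDataArray>\n',
      '<binaryDataArray encodedLength="', nchar(inb), '">\n',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>\n',
      '<binary>', inb, '</binary>\n</binaryDataArray>\n',
      '</binaryDataArrayList>\n</spectrum>'
    )
  }
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">\n',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>\n',
    '</cvList>\n',
    '<fileDescription>\n<fileContent>\n',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
    '</fileContent>\n</fileDescription>\n',
    '<softwareList count="1">\n',
    '<software id="stitchdims" version="0.1.0">\n',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="stitchdims"/>\n',
    '</software>\n</softwareList>\n',
    '<instrumentConfigurationList count="1">\n',
    '<instrumentConfiguration id="IC1">\n',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>\n',
    '</instrumentConfiguration>\n</instrumentConfigurationList>\n',
    '<dataProcessingList count="1">\n',
    '<dataProcessing id="DP1">\n<processingMethod order="1" softwareRef="stitchdims">\n',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>\n',
    '</processingMethod>\n</dataProcessing>\n</dataProcessingList>\n',
    '<run id="R1" defaultInstrumentConfigurationRef="IC1">\n',
    '<spectrumList count="', nrow(keys), '" defaultDataProcessingRef="DP1">\n',
    paste(spectra, collapse = "\n"), '\n',
    '</spectrumList>\n</run>\n</mzML>\n'
  )
  writeLines(doc, path, sep = "")
  invisible(path)
}
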