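# Putative annotation of features by accurate mass: every
# (compound, adduct) whose theoretical m/z lies within the ppm tolerance
# of a feature is reported. Mass-only evidence -- annotations are
# putative and deliberately non-unique.

#' Annotate features by accurate mass
#'
#' Builds the theoretical m/z of every compound under every adduct of
#' the requested ionisation mode and matches features against them with
#' a sorted interval search. All matches within tolerance are reported,
#' ranked per feature by absolute ppm error. Intensities play no role.
#'
#' @param fm a [feature_matrix()], or a numeric vector of feature m/z
#'   values.
#' @param compounds data.frame with `id`, `name` and `monoisotopic_mass`
#'   and/or `formula` (see [read_compound_table()]).
#' @param mode `"positive"` or `"negative"`; selects the adduct set.
#' @param tolerance_ppm mass tolerance (default 5 ppm).
#' @param adducts optional adduct-name subset overriding the mode's full
#'   set.
#' @return data.frame of class `annotation_table`: `feature_id`,
#'   `observed_mz`, `compound_id`, `compound_name`, `adduct`,
#'   `theoretical_mz`, `ppm_error`; attributes `n_annotated` /
#'   `n_features` give the summary counts.
#' @export
annotate_features <- function(fm, compounds, mode = c("negative", "positive"),
                              tolerance_ppm = 5, adducts = NULL) {
  mode <- match.arg(mode)
  if (inherits(fm, "feature_matrix")) {
    feature_id <- fm$features$feature_id
    mz <- fm$features$mz
  } else {
    mz <- as.numeric(fm)
    feature_id <- if (is.null(names(fm))) sprintf("F%05d", seq_along(mz))
                  else names(fm)
  }
  if (!"monoisotopic_mass" %in% names(compounds)) {
    compounds$monoisotopic_mass <- formula_mass(compounds$formula)
  }
  fill <- is.na(compounds$monoisotopic_mass)
  if (any(fill)) {
    compounds$monoisotopic_mass[fill] <- formula_mass(compounds$formula[fill])
  }
  rules <- adduct_rules(mode)
  if (!is.null(adducts)) {
    rules <- rules[rules$name %in% adducts, , drop = FALSE]
  }
  if (nrow(rules) == 0) {
    stop("no adduct rules configured for mode '", mode, "'", call. = FALSE)
  }
  empty <- data.frame(feature_id = character(0), observed_mz = numeric(0),
                      compound_id = character(0), compound_name = character(0),
                      adduct = character(0), theoretical_mz = numeric(0),
                      ppm_error = numeric(0), stringsAsFactors = FALSE)
  if (nrow(compounds) == 0 || length(mz) == 0) {
    out <- empty
  } else {
    mass_rep <- rep(compounds$monoisotopic_mass, each = nrow(rules))
    mult_rep <- rep(rules$multiplicity, times = nrow(compounds))
    shift_rep <- rep(rules$mass_shift, times = nrow(compounds))
    theo <- data.frame(
      compound_id = rep(compounds$id, each = nrow(rules)),
      compound_name = rep(compounds$name, each = nrow(rules)),
      adduct = rep(rules$name, times = nrow(compounds)),
      theoretical_mz = mult_rep * mass_rep + shift_rep,
      stringsAsFactors = FALSE
    )
    theo <- theo[theo$theoretical_mz > 0, , drop = FALSE]
    theo <- theo[order(theo$theoretical_mz), , drop = FALSE]
    tm <- theo$theoretical_mz
    # |1e6 (obs - theo)/theo| <= tol  <=>  theo in [obs/(1+t), obs/(1-t)]
    t <- tolerance_ppm * 1e-6
    lo <- findInterval(mz / (1 + t), tm, left.open = TRUE) + 1L
    hi <- findInterval(mz / (1 - t), tm)
    hits <- which(hi >= lo)
    rows <- lapply(hits, function(i) {
      idx <- lo[i]:hi[i]
      data.frame(feature_id = feature_id[i], observed_mz = mz[i],
                 compound_id = theo$compound_id[idx],
                 compound_name = theo$compound_name[idx],
                 adduct = theo$adduct[idx],
                 theoretical_mz = tm[idx],
                 ppm_error = ppm_error(mz[i], tm[idx]),
                 stringsAsFactors = FALSE)
    })
    out <- if (length(rows)) do.call(rbind, rows) else empty
    if (nrow(out)) {
      out <- out[order(match(out$feature_id, feature_id), abs(out$ppm_error)), ]
      rownames(out) <- NULL
    }
  }
  class(out) <- c("annotation_table", class(out))
  attr(out, "n_annotated") <- length(unique(out$feature_id))
  attr(out, "n_features") <- length(mz)
  attr(out, "tolerance_ppm") <- tolerance_ppm
  out
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("annotation_table: ", attr(x, "n_annotated"), " of ",
      attr(x, "n_features"), " features annotated at ",
      attr(x, "tolerance_ppm"), " ppm (", nrow(x), " records)\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10), row.names = FALSE)
  invisible(x)
}
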