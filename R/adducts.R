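# Monoisotopic atomic masses (Da), CODATA/AME2020 values.
.ATOMIC_MASS <- c(
  H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, Na = 22.9897692809, K = 38.96370668,
  Cl = 34.96885268, F = 18.99840322, Br = 78.9183371, I = 126.904473,
  Se = 73.9224764, Si = 27.9769265325, Ca = 39.96259098, Mg = 23.985041700,
  Fe = 55.9349375, Zn = 63.9291422, B = 11.0093054, Li = 7.01600455
)

.ELECTRON_MASS <- 0.000548579909

#' Monoisotopic mass of a molecular formula
#'
#' Parses a Hill-style molecular formula (e.g. `"C10H17N3O6S"`) and sums
#' monoisotopic atomic masses from the bundled table. Only neutral,
#' non-isotope-labelled formulas are supported.
#'
#' @param formula character vector of molecular formulas.
#' @return numeric vector of monoisotopic masses in Da.
#' @examples
#' formula_mass("C10H17N3O6S")  # glutathione, ~307.0838 Da
#' @export
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_real_)
    f <- gsub("[[:space:]]", "", f)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(f)) {
      stop("cannot parse molecular formula: '", f, "'", call. = FALSE)
    }
    total <- 0
    for (tok in toks) {
      el <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
      n <- sub("^[A-Z][a-z]?", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!el %in% names(.ATOMIC_MASS)) {
        stop("unknown element '", el, "' in formula '", f, "'", call. = FALSE)
      }
      total <- total + n * .ATOMIC_MASS[[el]]
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

.formula_shift <- function(add = "", remove = "", charge = 0L) {
  # electron bookkeeping: a +1 ion has lost one electron, a -1 ion gained one
  s <- 0
  if (nzchar(add)) s <- s + formula_mass(add)
  if (nzchar(remove)) s <- s - formula_mass(remove)
  s - charge * .ELECTRON_MASS
}

#' Built-in electrospray adduct rules
#'
#' The eight singly-charged adduct rules used for putative annotation of
#' DIMS features: `[M+H]+`, `[M+Na]+`, `[M+NH4]+` in positive ionisation
#' mode and `[M-H]-`, `[M+Cl]-`, `[M+Hac-H]-`, `[M+Na-2H]-`, `[M+K-2H]-`
#' in negative mode. `Hac` is acetic acid (CH3COOH), consistent with an
#' ammonium-acetate resuspension buffer. Mass shifts are computed from the
#' bundled monoisotopic atomic mass table and include the electron mass.
#'
#' @param mode `"positive"`, `"negative"` or `"both"` (default).
#' @return data.frame with columns `name`, `mass_shift` (Da, signed),
#'   `charge_sign`, `multiplicity`, `mode`.
#' @export
adduct_rules <- function(mode = c("both", "positive", "negative")) {
  mode <- match.arg(mode)
  rules <- data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+NH4]+",
             "[M-H]-", "[M+Cl]-", "[M+Hac-H]-", "[M+Na-2H]-", "[M+K-2H]-"),
    mass_shift = c(
      .formula_shift(add = "H", charge = 1L),
      .formula_shift(add = "Na", charge = 1L),
      .formula_shift(add = "NH4", charge = 1L),
      .formula_shift(remove = "H", charge = -1L),
      .formula_shift(add = "Cl", charge = -1L),
      .formula_shift(add = "C2H4O2", remove = "H", charge = -1L),
      .formula_shift(add = "Na", remove = "H2", charge = -1L),
      .formula_shift(add = "K", remove = "H2", charge = -1L)
    ),
    charge_sign = c("+", "+", "+", "-", "-", "-", "-", "-"),
    multiplicity = 1L,
    mode = c(rep("positive", 3), rep("negative", 5)),
    stringsAsFactors = FALSE
  )
  if (mode != "both") rules <- rules[rules$mode == mode, , drop = FALSE]
  rownames(rules) <- NULL
  rules
}

#' Theoretical m/z of an adduct of a neutral molecule
#'
#' @param monoisotopic_mass neutral monoisotopic mass in Da (> 0).
#' @param rule adduct rule name (see [adduct_rules()]) or a one-row subset
#'   of the rule table.
#' @return theoretical m/z in Da (vectorised over `monoisotopic_mass`).
#' @examples
#' adduct_mz(307.08380628, "[M+K-2H]-")
#' @export
adduct_mz <- function(monoisotopic_mass, rule) {
  stopifnot(all(monoisotopic_mass > 0))
  if (is.character(rule)) {
    rules <- adduct_rules()
    idx <- match(rule, rules$name)
    if (anyNA(idx)) {
      stop("unknown adduct rule '", paste(rule[is.na(idx)], collapse = "', '"),
           "'; available: ", paste(rules$name, collapse = ", "), call. = FALSE)
    }
    rule <- rules[idx, , drop = FALSE]
  }
  rule$multiplicity * monoisotopic_mass + rule$mass_shift
}

#' Signed relative mass error in parts per million
#'
#' @param observed observed m/z (Da).
#' @param theoretical theoretical m/z (Da, > 0).
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  1e6 * (observed - theoretical) / theoretical
}
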