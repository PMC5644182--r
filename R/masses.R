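# Monoisotopic masses of the elements commonly seen in fungal secondary
# metabolites (IUPAC 2021 atomic mass evaluation, most abundant isotope).
.monoisotopic <- c(
  C  = 12,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  Cl = 34.96885268,
  Br = 78.9183371,
  F  = 18.99840322,
  I  = 126.904473,
  Na = 22.98976928,
  K  = 38.96370668,
  Si = 27.97692653
)

.proton_mass <- 1.00727646688
.electron_mass <- 0.00054857990

# m/z offsets of the common positive electrospray adducts (singly charged)
.adduct_offsets <- c(
  "[M+H]+"   = 1.00727646688,
  "[M+Na]+"  = 22.98976928 - 0.00054857990,
  "[M+NH4]+" = 14.0030740048 + 4 * 1.00782503207 - 0.00054857990
)

#' Parse an elemental formula into element counts
#'
#' Accepts Hill-notation formulas such as `"C17H17ClO6"`. Only single-letter
#' and two-letter element symbols with optional integer counts are supported;
#' no parentheses, charges or isotope labels.
#'
#' @param formula A single character string.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula)) {
    abort("`formula` must be a single string.", class = "fermkin_formula_error")
  }
  s <- gsub("[[:space:]]", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  pieces <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (!length(pieces) || paste(pieces, collapse = "") != s) {
    abort(paste0("Cannot parse formula: '", formula, "'"),
          class = "fermkin_formula_error")
  }
  el <- sub("[0-9]+$", "", pieces)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", pieces),
                           sub("^[A-Za-z]+", "", pieces), "1"))
  unknown <- setdiff(el, names(.monoisotopic))
  if (length(unknown)) {
    abort(paste0("Unknown element(s) in '", formula, "': ",
                 paste(unknown, collapse = ", ")),
          class = "fermkin_formula_error")
  }
  counts <- tapply(cnt, factor(el, levels = unique(el)), sum)
  setNames(as.integer(counts), names(counts))
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula Character vector of elemental formulas.
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' monoisotopic_mass("C17H17ClO6") # griseofulvin, 352.0714 Da
#' @export
monoisotopic_mass <- function(formula) {
  vapply(formula, function(f) {
    cnt <- parse_formula(f)
    sum(.monoisotopic[names(cnt)] * cnt)
  }, numeric(1), USE.NAMES = FALSE)
}

#' m/z of a singly charged adduct ion
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param adduct One of `"[M+H]+"`, `"[M+Na]+"`, `"[M+NH4]+"`.
#' @return Numeric m/z.
#' @examples
#' adduct_mz(352.071366, "[M+H]+")
#' @export
adduct_mz <- function(mass, adduct = "[M+H]+") {
  adduct <- match.arg(adduct, names(.adduct_offsets), several.ok = FALSE)
  mass + .adduct_offsets[[adduct]]
}
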