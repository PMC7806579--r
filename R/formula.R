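#' Parse an elemental formula
#'
#' Parses a plain elemental formula string such as `"C5H9NO2"` into a named
#' integer vector of element counts. The grammar is a sequence of element
#' symbols (one capital letter optionally followed by one lowercase letter),
#' each with an optional count of up to four digits; an omitted count means 1.
#' Parentheses, isotope labels and charges are not supported.
#'
#' @param text Formula string, e.g. `"C5H9NO2"` or `"H2O"`.
#' @return A `chem_formula`: named integer vector, element symbol -> count,
#'   all counts positive.
#' @examples
#' parse_formula("C5H9NO2") # proline
#' parse_formula("H2O")
#' @seealso [monoisotopic_mass()]
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  # tokenize: element symbol + optional count
  m <- gregexpr("[A-Z][a-z]?[0-9]{0,4}", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop(sprintf("cannot parse formula '%s'", text))
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- sub("^[A-Z][a-z]?", "", tokens)
  cnts <- ifelse(cnts == "", 1L, as.integer(cnts))
  unknown <- setdiff(syms, names(.ELEMENT_MASSES))
  if (length(unknown))
    stop(sprintf("unknown element symbol(s): %s", paste(unknown, collapse = ", ")))
  if (any(cnts == 0L))
    stop("zero element counts are not allowed")
  counts <- tapply(cnts, factor(syms, levels = unique(syms)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  structure(out, class = "chem_formula")
}

#' @export
format.chem_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula>", format(x), "=", sprintf("%.4f Da", monoisotopic_mass(x)), "\n")
  invisible(x)
}

as_formula <- function(f) {
  if (inherits(f, "chem_formula")) f else parse_formula(f)
}

#' Monoisotopic mass of a formula
#'
#' Sum of element count times monoisotopic element mass, in Da.
#'
#' @param f A `chem_formula` from [parse_formula()], or a formula string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C5H9NO2") # proline, 115.0633
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  sum(.ELEMENT_MASSES[names(f)] * unclass(f))
}

# Multiset sum of two formulas (used by tests and the heterodimer scan).
formula_sum <- function(f1, f2) {
  f1 <- as_formula(f1); f2 <- as_formula(f2)
  all_sym <- union(names(f1), names(f2))
  out <- integer(length(all_sym)); names(out) <- all_sym
  out[names(f1)] <- out[names(f1)] + unclass(f1)
  out[names(f2)] <- out[names(f2)] + unclass(f2)
  structure(out, class = "chem_formula")
}
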