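#' Parse an elemental formula string
#'
#' Parses a Hill-style molecular formula such as `"C33H62N6O13"` into a
#' named integer vector of element counts. Only elements of the configured
#' alphabet (by default C, H, N, O, S) are accepted; counts default to 1
#' when omitted (`"H2O"` has one oxygen).
#'
#' @param text formula string, e.g. `"C6H10O2"`.
#' @param alphabet character vector of allowed element symbols.
#' @return An object of class `chem_formula`: a named integer vector of
#'   strictly positive element counts.
#' @examples
#' parse_formula("C6H10O2")
#' parse_formula("H2O")
#' @seealso [format_formula()], [monoisotopic_mass()]
#' @export
parse_formula <- function(text, alphabet = c("C", "H", "N", "O", "S", "Fe")) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  parts <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(nchar(parts)) != nchar(text))
    stop("malformed formula: '", text, "'")
  counts <- integer(0)
  for (p in parts) {
    sym <- sub("[0-9]*$", "", p)
    num <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% alphabet)
      stop("unknown element symbol '", sym, "' in formula '", text, "'")
    if (is.na(n) || n <= 0L)
      stop("malformed count for element '", sym, "' in formula '", text, "'")
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  as_chem_formula(counts)
}

as_chem_formula <- function(counts) {
  counts <- counts[counts > 0L]
  storage.mode(counts) <- "integer"
  structure(counts[hill_order(names(counts))], class = "chem_formula")
}

## Hill convention: C first, then H, then other elements alphabetically
hill_order <- function(syms) {
  rest <- sort(setdiff(syms, c("C", "H")))
  intersect(c("C", "H", rest), syms)
}

#' Format an elemental formula as a Hill-notation string
#'
#' @param f a `chem_formula` (named integer vector of element counts).
#' @return A single string; the empty formula formats as `""`.
#' @examples
#' format_formula(parse_formula("H10C6O2"))  # "C6H10O2"
#' @export
format_formula <- function(f) {
  f <- coerce_formula(f)
  f <- f[f > 0L]
  if (length(f) == 0L) return("")
  syms <- hill_order(names(f))
  paste0(vapply(syms, function(s)
    paste0(s, if (f[[s]] > 1L) f[[s]] else ""), character(1)), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

coerce_formula <- function(f) {
  if (is.character(f)) return(parse_formula(f))
  if (is.null(names(f)) && length(f) > 0L)
    stop("formula must be a named count vector or a string")
  if (any(f < 0)) stop("element counts must be non-negative")
  f
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum over elements of count times the monoisotopic atomic mass from
#' [mass_constants()]. Accepts a formula string or a named count vector.
#'
#' @param f formula string or `chem_formula`.
#' @return Neutral monoisotopic mass in Da (0 for the empty formula).
#' @examples
#' monoisotopic_mass("C6H10O2")        # 114.0681
#' monoisotopic_mass("C33H62N6O13")    # 750.4375
#' @export
monoisotopic_mass <- function(f) {
  f <- coerce_formula(f)
  if (length(f) == 0L) return(0)
  ms <- mass_constants()$masses
  unknown <- setdiff(names(f), names(ms))
  if (length(unknown))
    stop("no mass for element(s): ", paste(unknown, collapse = ", "))
  sum(ms[names(f)] * as.numeric(f))
}

#' m/z of the protonated molecular ion [M+H]+
#'
#' Adds one proton mass to a neutral monoisotopic mass; a single positive
#' charge is assumed throughout the package. The electron mass is not
#' subtracted (error < 1 ppm above m/z 100).
#'
#' @param neutral_mass neutral monoisotopic mass in Da (>= 0), or a formula
#'   string / `chem_formula`, in which case its mass is computed first.
#' @return m/z of [M+H]+.
#' @examples
#' protonated_mz("C4H7NO")   # 86.0600
#' protonated_mz(750.4375)   # 751.4448
#' @export
protonated_mz <- function(neutral_mass) {
  if (!is.numeric(neutral_mass)) neutral_mass <- monoisotopic_mass(neutral_mass)
  if (neutral_mass < 0) stop("neutral mass must be non-negative")
  neutral_mass + mass_constants()$proton
}

#' m/z of the protonated ferric complex [M - 3H + Fe + H]+
#'
#' A tris-hydroxamate siderophore chelates Fe(III) by losing three protons,
#' so the neutral holo species is the tris-deprotonated ferric complex
#' M - 3H + Fe. Its protonated ion therefore sits a constant
#' 56Fe - 3 H = 52.91146 Da above the apo [M+H]+ ion, independent of M.
#'
#' @param apo_neutral_mass neutral monoisotopic mass of the apo (metal-free)
#'   siderophore in Da, or a formula; must exceed three hydrogen masses.
#' @return m/z of the singly protonated 56Fe complex.
#' @examples
#' ferric_complex_mz(750.4375)                        # 804.3562
#' ferric_complex_mz(750.4375) - protonated_mz(750.4375)  # 52.91146
#' @export
ferric_complex_mz <- function(apo_neutral_mass) {
  if (!is.numeric(apo_neutral_mass))
    apo_neutral_mass <- monoisotopic_mass(apo_neutral_mass)
  k <- mass_constants()
  if (apo_neutral_mass <= 3 * k$masses[["H"]])
    stop("apo neutral mass too small to lose three protons")
  apo_neutral_mass + k$holo_shift + k$proton
}

#' Ring and double-bond equivalents
#'
#' RDBE = (2 C + 2 + N - H) / 2 for CHNOS formulas; O and S do not
#' contribute. Used as a plausibility filter in formula decomposition.
#'
#' @param f formula string or `chem_formula`.
#' @return RDBE as a double (can be half-integer for odd-electron species).
#' @examples
#' rdbe("C6H10O2")       # 2
#' rdbe("C35H65N7O10")   # 7
#' @export
rdbe <- function(f) {
  f <- coerce_formula(f)
  g <- function(s) if (s %in% names(f)) as.numeric(f[[s]]) else 0
  (2 * g("C") + 2 + g("N") - g("H")) / 2
}

#' Parts-per-million mass error
#'
#' @param observed observed mass or m/z.
#' @param theoretical theoretical mass or m/z (> 0).
#' @return Signed error, 1e6 * (observed - theoretical) / theoretical.
#' @export
ppm_error <- function(observed, theoretical) {
  1e6 * (observed - theoretical) / theoretical
}
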