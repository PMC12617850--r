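#' Hydroxamate building-block library
#'
#' Reads a building-block library CSV (columns `name`, `fragment_formula`,
#' `loss_formula`, `ion_type`, `provenance`) and computes the theoretical
#' fragment-ion m/z and neutral-loss mass from the formulas. The default
#' library ships with the package and covers the diagnostic fragments of
#' hydroxamate siderophores built from N5-hydroxyornithine: the
#' hydroxyornithine-derived fragment (protonated at m/z 131.0815, residue
#' loss 130.0742), the N5-formyl-N5-hydroxyornithine fragment (157.0608,
#' loss 158.0691), the hexanoyl-derived C6H10O2 fragment (115.0754, loss
#' 114.0681) and the C4H7NO fragment (86.0600). Elemental formulas of the
#' two ornithine-derived entries are inferred from the measured masses
#' (their `provenance` column says so); the C6H10O2 and C4H7NO formulas
#' are reported directly.
#'
#' @param path CSV path; defaults to the library shipped in `extdata`.
#' @return data.frame with the CSV columns plus `fragment_mz` and
#'   `loss_mass` (Da) computed from the formulas.
#' @export
building_block_library <- function(path = system.file("extdata",
                                                      "building_blocks.csv",
                                                      package = "sideroscan")) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "fragment_formula", "loss_formula", "ion_type")
  missing <- setdiff(need, names(lib))
  if (length(missing))
    stop("library missing column(s): ", paste(missing, collapse = ", "))
  lib$fragment_mz <- vapply(seq_len(nrow(lib)), function(i) {
    m <- monoisotopic_mass(lib$fragment_formula[i])
    if (identical(lib$ion_type[i], "protonated")) protonated_mz(m) else m
  }, numeric(1))
  lib$loss_mass <- vapply(lib$loss_formula, monoisotopic_mass, numeric(1))
  lib
}

## tolerance rule used for fragment matching: 5 ppm or 0.003 Da,
## whichever is larger at the given m/z
match_tol <- function(mz, tol_ppm = 5, tol_da = 0.003) {
  pmax(tol_da, tol_ppm * 1e-6 * mz)
}

#' Annotate an MS/MS spectrum against a building-block library
#'
#' Every peak is compared to each block's theoretical fragment-ion m/z,
#' and every neutral loss (precursor m/z minus peak m/z) to each block's
#' loss mass, at a tolerance of 5 ppm or 0.003 Da, whichever is larger.
#'
#' @param s a [fragment_spectrum()] with a known precursor m/z.
#' @param library a [building_block_library()] data.frame.
#' @param tol_ppm,tol_da tolerance parameters.
#' @return data.frame of hits with columns `spectrum_id`, `kind`
#'   (`"fragment"` or `"neutral_loss"`), `block`, `observed` (peak m/z or
#'   loss), `theoretical`, `error_ppm`, `peak_mz`, `peak_intensity`.
#' @examples
#' s <- fragment_spectrum("x", 751.4448,
#'                        cbind(c(86.0600, 131.0815, 637.3767), c(1, 0.5, 0.3)))
#' annotate_spectrum(s)
#' @export
annotate_spectrum <- function(s, library = building_block_library(),
                              tol_ppm = 5, tol_da = 0.003) {
  empty <- data.frame(spectrum_id = character(0), kind = character(0),
                      block = character(0), observed = numeric(0),
                      theoretical = numeric(0), error_ppm = numeric(0),
                      peak_mz = numeric(0), peak_intensity = numeric(0),
                      stringsAsFactors = FALSE)
  if (!n_peaks(s)) return(empty)
  mz <- s$peaks[, "mz"]; int <- s$peaks[, "intensity"]
  loss <- s$precursor_mz - mz
  out <- list()
  for (b in seq_len(nrow(library))) {
    fm <- library$fragment_mz[b]
    hit <- which(abs(mz - fm) <= match_tol(fm, tol_ppm, tol_da))
    for (i in hit)
      out[[length(out) + 1L]] <- data.frame(
        spectrum_id = s$spectrum_id, kind = "fragment",
        block = library$name[b], observed = mz[i], theoretical = fm,
        error_ppm = ppm_error(mz[i], fm), peak_mz = mz[i],
        peak_intensity = int[i], stringsAsFactors = FALSE)
    lm <- library$loss_mass[b]
    hit <- which(loss > 0 & abs(loss - lm) <= match_tol(lm, tol_ppm, tol_da))
    for (i in hit)
      out[[length(out) + 1L]] <- data.frame(
        spectrum_id = s$spectrum_id, kind = "neutral_loss",
        block = library$name[b], observed = loss[i], theoretical = lm,
        error_ppm = ppm_error(loss[i], lm), peak_mz = mz[i],
        peak_intensity = int[i], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Summarise hydroxamate MS/MS evidence for a candidate spectrum
#'
#' Counts the distinct building blocks matched by [annotate_spectrum()]
#' and flags the spectrum as hydroxamate-consistent when at least
#' `min_blocks` distinct blocks hit (fragments or neutral losses). Major
#' peaks (above `major_fraction` of the base peak) with no annotation are
#' listed as unexplained.
#'
#' @param s the annotated [fragment_spectrum()].
#' @param hits annotation table from [annotate_spectrum()]; computed from
#'   `s` when omitted.
#' @param min_blocks distinct-block threshold for the consistency flag,
#'   default 2.
#' @param major_fraction relative-intensity cutoff defining a "major"
#'   peak, default 0.05.
#' @param library building-block library used when `hits` is computed here.
#' @return list of class `hydroxamate_evidence`: `spectrum_id`,
#'   `n_blocks`, `blocks`, `consistent`, `hits`, `unexplained_major_peaks`.
#' @export
score_hydroxamate_evidence <- function(s, hits = NULL, min_blocks = 2,
                                       major_fraction = 0.05,
                                       library = building_block_library()) {
  if (is.null(hits)) hits <- annotate_spectrum(s, library)
  blocks <- unique(hits$block)
  major <- if (n_peaks(s)) {
    mz <- unname(s$peaks[, "mz"]); int <- s$peaks[, "intensity"]
    mz[int >= major_fraction * max(int) & !mz %in% hits$peak_mz]
  } else numeric(0)
  structure(list(spectrum_id = s$spectrum_id, n_blocks = length(blocks),
                 blocks = blocks, consistent = length(blocks) >= min_blocks,
                 hits = hits, unexplained_major_peaks = major),
            class = "hydroxamate_evidence")
}

#' @export
print.hydroxamate_evidence <- function(x, ...) {
  cat("Hydroxamate evidence for ", x$spectrum_id, ": ", x$n_blocks,
      " distinct block(s) [",
      if (x$consistent) "hydroxamate-consistent" else "not flagged",
      "]\n", sep = "")
  if (x$n_blocks) cat("  blocks:", paste(x$blocks, collapse = ", "), "\n")
  if (length(x$unexplained_major_peaks))
    cat("  unexplained major peaks:",
        paste(round(x$unexplained_major_peaks, 4), collapse = ", "), "\n")
  invisible(x)
}
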