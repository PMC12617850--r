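#' Construct an MS/MS fragment spectrum
#'
#' @param spectrum_id spectrum identifier.
#' @param precursor_mz precursor ion m/z.
#' @param peaks two-column matrix or data.frame of `(mz, intensity)`;
#'   intensities must be positive. Peaks are stored sorted by m/z.
#' @param precursor_rt precursor retention time (min), optional.
#' @param feature_id linked MS1 feature id, optional.
#' @return An object of class `fragment_spectrum`.
#' @export
fragment_spectrum <- function(spectrum_id, precursor_mz, peaks,
                              precursor_rt = NA_real_,
                              feature_id = NA_character_) {
  peaks <- as.matrix(peaks)
  if (ncol(peaks) != 2L) stop("peaks must have two columns (mz, intensity)")
  colnames(peaks) <- c("mz", "intensity")
  if (nrow(peaks)) {
    if (any(!is.finite(peaks)) || any(peaks[, "intensity"] <= 0))
      stop("peak intensities must be positive and finite")
    peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  }
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = precursor_mz, precursor_rt = precursor_rt,
                 peaks = peaks, feature_id = as.character(feature_id)),
            class = "fragment_spectrum")
}

#' @export
print.fragment_spectrum <- function(x, ...) {
  cat("<fragment_spectrum> ", x$spectrum_id, ": precursor m/z ",
      round(x$precursor_mz, 4), ", ", nrow(x$peaks), " peak(s)\n", sep = "")
  invisible(x)
}

n_peaks <- function(s) nrow(s$peaks)
base_peak_intensity <- function(s)
  if (n_peaks(s)) max(s$peaks[, "intensity"]) else 0

#' Read MS/MS spectra from an MGF file
#'
#' Minimal Mascot Generic Format reader covering the fields this package
#' writes: BEGIN/END IONS blocks with TITLE (carrying the linked feature
#' id), PEPMASS, RTINSECONDS and peak lines.
#'
#' @param path MGF file path.
#' @return List of [fragment_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts))
    stop("malformed MGF: unbalanced BEGIN/END IONS")
  lapply(seq_along(starts), function(b) {
    block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    hdr <- block[kv]
    keys <- toupper(sub("=.*$", "", hdr))
    vals <- sub("^[^=]*=", "", hdr)
    get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    pk <- block[!kv & nzchar(trimws(block))]
    peaks <- if (length(pk)) {
      m <- do.call(rbind, lapply(strsplit(trimws(pk), "[ \t]+"),
                                 function(x) as.numeric(x[1:2])))
      m
    } else matrix(numeric(0), 0, 2)
    title <- get("TITLE")
    rt <- suppressWarnings(as.numeric(get("RTINSECONDS"))) / 60
    pep <- suppressWarnings(as.numeric(strsplit(get("PEPMASS"), "[ \t]+")[[1]][1]))
    fid <- if (!is.na(title) && grepl("feature_id=", title))
      sub(".*feature_id=([^; ]+).*", "\\1", title) else title
    fragment_spectrum(spectrum_id = if (is.na(title)) paste0("spec", b) else title,
                      precursor_mz = pep, peaks = peaks,
                      precursor_rt = rt, feature_id = fid)
  })
}

#' Write MS/MS spectra to an MGF file
#'
#' @param spectra list of [fragment_spectrum()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s;feature_id=%s", s$spectrum_id, s$feature_id),
               con)
    writeLines(sprintf("PEPMASS=%.5f", s$precursor_mz), con)
    if (is.finite(s$precursor_rt))
      writeLines(sprintf("RTINSECONDS=%.3f", s$precursor_rt * 60), con)
    writeLines("CHARGE=1+", con)
    if (n_peaks(s))
      writeLines(sprintf("%.5f %.6g", s$peaks[, "mz"], s$peaks[, "intensity"]),
                 con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Remove a ubiquitous contaminant ion from a spectrum
#'
#' Drops every peak within `tol_da` of the contaminant m/z. A prominent
#' ion at m/z 202.080, present in all MS/MS spectra independent of the
#' precursor, is the default target.
#'
#' @param s a [fragment_spectrum()].
#' @param contaminant_mz contaminant m/z, default 202.080.
#' @param tol_da absolute tolerance (Da), default 0.003.
#' @return The spectrum without the contaminant peak(s).
#' @export
remove_contaminant <- function(s, contaminant_mz = 202.080, tol_da = 0.003) {
  if (!n_peaks(s)) return(s)
  keep <- abs(s$peaks[, "mz"] - contaminant_mz) > tol_da
  s$peaks <- s$peaks[keep, , drop = FALSE]
  s
}

#' Filter spectrum peaks by windowed rank and relative intensity
#'
#' A peak survives iff it ranks among the `top_k` most intense peaks
#' within the `window_da`-wide window centred on it (a sliding window, so
#' peaks within +/- window/2 compete) AND its intensity is at least
#' `min_rel_intensity` of the base peak. Defaults keep the top five ions
#' per 50 Da window and drop ions below 0.1% of the most abundant
#' fragment.
#'
#' @param s a [fragment_spectrum()].
#' @param top_k maximum rank within the window, default 5.
#' @param window_da window width in Da, default 50.
#' @param min_rel_intensity relative intensity floor, default 0.001.
#' @return The filtered spectrum. The operation is idempotent.
#' @export
filter_peaks <- function(s, top_k = 5, window_da = 50,
                         min_rel_intensity = 0.001) {
  stopifnot(top_k > 0, window_da > 0, min_rel_intensity >= 0)
  if (!n_peaks(s)) return(s)
  mz <- s$peaks[, "mz"]; int <- s$peaks[, "intensity"]
  half <- window_da / 2
  keep <- vapply(seq_along(mz), function(i) {
    inwin <- abs(mz - mz[i]) <= half
    sum(int[inwin] > int[i]) < top_k
  }, logical(1))
  keep <- keep & int >= min_rel_intensity * max(int)
  s$peaks <- s$peaks[keep, , drop = FALSE]
  s
}
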