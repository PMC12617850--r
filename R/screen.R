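#' Configuration for the siderophore screen
#'
#' Collects the tolerances and switches of [screen_siderophores()]. The
#' blank-subtraction threshold (0.01% of the sample area), the mass
#' tolerance (0.003 Da) and the scan range (m/z 80-1500) follow the
#' acquisition and processing settings of the study design this screen
#' implements; the isotope-ratio window and RT windows are documented
#' package choices.
#'
#' @param blank_fraction blank-removal area-ratio threshold, default 1e-4.
#' @param mz_tol_ppm cross-run feature-matching tolerance (ppm), default 5.
#' @param mz_tol_da exact-mass tolerance (Da) for isotope spacing and
#'   apo/holo pairing, default 0.003.
#' @param rt_match_tol cross-run RT matching tolerance (min), default 0.2.
#' @param rt_pair_window apo/holo RT co-occurrence window (min), default 2.
#' @param ratio_window 54Fe/56Fe intensity-ratio acceptance window,
#'   default `c(0.02, 0.15)`.
#' @param require_apo require both the apo species and the ferric complex
#'   (default `TRUE`); when `FALSE`, an iron-pattern hit alone qualifies.
#' @param decompose_tol_ppm ppm tolerance for formula decomposition of the
#'   apo neutral mass, default 5.
#' @param bounds decomposition bounds, see [default_decomposition_bounds()].
#' @param scan_range acquisition m/z range, default `c(80, 1500)`.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(blank_fraction = 1e-4, mz_tol_ppm = 5,
                          mz_tol_da = 0.003, rt_match_tol = 0.2,
                          rt_pair_window = 2.0,
                          ratio_window = c(0.02, 0.15),
                          require_apo = TRUE, decompose_tol_ppm = 5,
                          bounds = default_decomposition_bounds(),
                          scan_range = c(80, 1500)) {
  structure(list(blank_fraction = blank_fraction, mz_tol_ppm = mz_tol_ppm,
                 mz_tol_da = mz_tol_da, rt_match_tol = rt_match_tol,
                 rt_pair_window = rt_pair_window, ratio_window = ratio_window,
                 require_apo = require_apo,
                 decompose_tol_ppm = decompose_tol_ppm, bounds = bounds,
                 scan_range = scan_range),
            class = "screen_config")
}

#' Screen an LC-MS feature table for iron-siderophore complexes
#'
#' Implements the three-criterion siderophore search on MS1 features:
#' (1) the natural 54Fe/56Fe isotope pattern on the ferric-complex ion,
#' (2) the exact mass difference of 52.91146 Da between the protonated apo
#' siderophore and its protonated ferric complex, and (3) optional MS/MS
#' corroboration, which is attached separately via
#' [score_hydroxamate_evidence()]. Control-run features are removed first
#' (area in control > 0.01% of the sample area), then iron-pattern hits
#' and apo/holo pairs are intersected, the apo neutral mass is decomposed
#' into candidate elemental formulas, and CH2/O analog relations among the
#' candidate apo masses are annotated.
#'
#' @param sample sample feature data.frame (see [read_features()]).
#' @param control optional control/blank feature data.frame.
#' @param envelopes optional isotopologue envelope table, see
#'   [find_iron_pattern_hits()].
#' @param config a [screen_config()].
#' @return An object of class `siderophore_screen`: a list with
#'   `candidates` (one row per accepted apo/holo pair, with m/z, RT, areas,
#'   mass errors, isotope ratio, top candidate formula), `family_links`
#'   (CH2/O mass-relations among candidates), `formulas` (named list of
#'   decomposition tables), `counts` (features at each stage) and `config`.
#' @examples
#' scn <- generate_scenario(scenario_config(seed = 1))
#' scr <- screen_siderophores(scn$sample, scn$control, scn$envelopes)
#' scr
#' @export
screen_siderophores <- function(sample, control = NULL, envelopes = NULL,
                                config = screen_config()) {
  sample <- validate_features(sample, config$scan_range)
  if (!is.null(control)) control <- validate_features(control, config$scan_range)
  n_in <- nrow(sample)
  kept <- blank_filter(sample, control, config$blank_fraction,
                       config$mz_tol_ppm, config$rt_match_tol)
  ## order-independence: work on a canonically sorted copy
  kept <- kept[order(kept$mz, kept$rt_min, kept$feature_id), , drop = FALSE]
  hits <- find_iron_pattern_hits(kept, envelopes,
                                 spacing_tol_da = config$mz_tol_da,
                                 ratio_window = config$ratio_window)
  pairs <- pair_apo_holo(kept, mz_tol_da = config$mz_tol_da,
                         rt_window = config$rt_pair_window)
  k <- mass_constants()

  if (config$require_apo) {
    cand <- pairs[pairs$holo_feature_id %in% hits$feature_id, , drop = FALSE]
  } else {
    hit_only <- hits[!hits$feature_id %in% pairs$holo_feature_id, , drop = FALSE]
    extra <- if (nrow(hit_only)) data.frame(
      apo_feature_id = NA_character_, holo_feature_id = hit_only$feature_id,
      mass_error_ppm = NA_real_, rt_shift = NA_real_, apo_fraction = 0,
      stringsAsFactors = FALSE) else NULL
    cand <- rbind(pairs[pairs$holo_feature_id %in% hits$feature_id, ,
                        drop = FALSE], extra)
  }

  if (nrow(cand)) {
    holo <- kept[match(cand$holo_feature_id, kept$feature_id), ]
    apo_mz <- ifelse(is.na(cand$apo_feature_id), NA_real_,
                     kept$mz[match(cand$apo_feature_id, kept$feature_id)])
    apo_rt <- ifelse(is.na(cand$apo_feature_id), NA_real_,
                     kept$rt_min[match(cand$apo_feature_id, kept$feature_id)])
    ## apo neutral mass, from the apo ion when present, else from the holo ion
    neutral <- ifelse(is.na(apo_mz), holo$mz - k$proton - k$holo_shift,
                      apo_mz - k$proton)
    ratio <- hits$abundance_ratio[match(cand$holo_feature_id, hits$feature_id)]
    candidates <- data.frame(
      apo_feature_id = cand$apo_feature_id,
      holo_feature_id = cand$holo_feature_id,
      apo_mz = apo_mz, holo_mz = holo$mz,
      apo_rt = apo_rt, holo_rt = holo$rt_min,
      apo_neutral_mass = neutral,
      pair_mass_error_ppm = cand$mass_error_ppm,
      fe_ratio = ratio, apo_fraction = cand$apo_fraction,
      stringsAsFactors = FALSE)
    candidates <- candidates[order(candidates$apo_neutral_mass), , drop = FALSE]
    rownames(candidates) <- NULL
    formulas <- lapply(candidates$apo_neutral_mass, function(m)
      decompose_mass(m, config$decompose_tol_ppm, config$bounds))
    names(formulas) <- candidates$holo_feature_id
    candidates$top_formula <- vapply(formulas, function(d)
      if (nrow(d)) d$formula[1] else NA_character_, character(1))
    candidates$n_formulas <- vapply(formulas, nrow, integer(1))
    links <- family_links(candidates, tol_da = config$mz_tol_da)
  } else {
    candidates <- data.frame(
      apo_feature_id = character(0), holo_feature_id = character(0),
      apo_mz = numeric(0), holo_mz = numeric(0), apo_rt = numeric(0),
      holo_rt = numeric(0), apo_neutral_mass = numeric(0),
      pair_mass_error_ppm = numeric(0), fe_ratio = numeric(0),
      apo_fraction = numeric(0), top_formula = character(0),
      n_formulas = integer(0), stringsAsFactors = FALSE)
    formulas <- list()
    links <- family_links(candidates, tol_da = config$mz_tol_da)
  }

  structure(list(candidates = candidates, family_links = links,
                 formulas = formulas,
                 counts = c(input = n_in, after_blank = nrow(kept),
                            iron_hits = nrow(hits), apo_holo_pairs = nrow(pairs),
                            candidates = nrow(candidates)),
                 config = config),
            class = "siderophore_screen")
}

## CH2 (14.01565 Da) and O (15.99491 Da) analog relations among candidates
family_links <- function(candidates, tol_da = 0.003) {
  k <- mass_constants()
  rel <- c(CH2 = unname(k$ch2), O = unname(k$o))
  out <- list()
  n <- nrow(candidates)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      d <- abs(candidates$apo_neutral_mass[j] - candidates$apo_neutral_mass[i])
      for (r in names(rel)) {
        if (abs(d - rel[[r]]) <= tol_da)
          out[[length(out) + 1L]] <- data.frame(
            from = candidates$holo_feature_id[i],
            to = candidates$holo_feature_id[j],
            relation = r, delta_mass = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(from = character(0), to = character(0),
                      relation = character(0), delta_mass = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' @export
print.siderophore_screen <- function(x, ...) {
  cat("Siderophore screen:", x$counts[["candidates"]],
      "candidate(s) from", x$counts[["input"]], "feature(s)\n")
  cat("  after blank removal:", x$counts[["after_blank"]],
      "| iron-pattern hits:", x$counts[["iron_hits"]],
      "| apo/holo pairs:", x$counts[["apo_holo_pairs"]], "\n")
  if (nrow(x$candidates)) {
    show <- x$candidates[, c("apo_mz", "holo_mz", "apo_rt", "holo_rt",
                             "fe_ratio", "top_formula")]
    print(cbind(round(show[1:5], 4), top_formula = show$top_formula))
  }
  invisible(x)
}

#' @export
summary.siderophore_screen <- function(object, ...) {
  cat("Stage counts:\n")
  print(object$counts)
  if (nrow(object$family_links)) {
    cat("Analog relations among candidates:\n")
    print(object$family_links)
  }
  invisible(object)
}

#' Plot a siderophore screen over the feature map
#'
#' Retention time versus m/z for the screened candidates; apo and holo
#' ions of each pair are connected.
#'
#' @param x a `siderophore_screen`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.siderophore_screen <- function(x, ...) {
  cc <- x$candidates
  if (!nrow(cc)) {
    graphics::plot(NA, xlim = c(0, 10), ylim = c(80, 1500),
                   xlab = "RT (min)", ylab = "m/z", main = "No candidates")
    return(invisible(x))
  }
  graphics::plot(c(cc$apo_rt, cc$holo_rt), c(cc$apo_mz, cc$holo_mz),
                 pch = rep(c(1, 19), each = nrow(cc)),
                 xlab = "RT (min)", ylab = "m/z",
                 main = "Siderophore candidates (open: apo, filled: Fe complex)",
                 ...)
  graphics::segments(cc$apo_rt, cc$apo_mz, cc$holo_rt, cc$holo_mz,
                     lty = 3, col = "grey40")
  invisible(x)
}
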