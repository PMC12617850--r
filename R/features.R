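#' Read an MS1 feature table from CSV
#'
#' Expected columns: `feature_id`, `mz`, `rt_min`, `area`, `polarity`.
#' Basic schema checks are applied (positive areas, non-negative retention
#' times, m/z inside the scan range).
#'
#' @param path CSV file path.
#' @param scan_range numeric length-2 acquisition m/z range, default
#'   `c(80, 1500)`.
#' @return data.frame of features.
#' @export
read_features <- function(path, scan_range = c(80, 1500)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_features(df, scan_range)
}

#' Write an MS1 feature table to CSV
#' @param features feature data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_features <- function(df, scan_range = c(80, 1500)) {
  need <- c("feature_id", "mz", "rt_min", "area", "polarity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("feature table missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) return(df)
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature_id in feature table")
  if (any(!is.finite(df$mz)) || any(df$mz < scan_range[1]) ||
      any(df$mz > scan_range[2]))
    stop("feature m/z outside scan range [", scan_range[1], ", ",
         scan_range[2], "]")
  if (any(!is.finite(df$area)) || any(df$area <= 0))
    stop("feature areas must be positive")
  if (any(!is.finite(df$rt_min)) || any(df$rt_min < 0))
    stop("retention times must be non-negative")
  df
}

#' Match features between two runs by m/z and retention time
#'
#' Greedy nearest matching: candidate cross-run pairs within the m/z and RT
#' tolerances are ranked by ppm distance, then RT distance, and accepted
#' one by one so that each feature on either side is matched at most once.
#'
#' @param a,b feature data.frames (`feature_id`, `mz`, `rt_min`, ...).
#' @param mz_tol_ppm m/z tolerance in ppm, default 5.
#' @param rt_tol RT tolerance in minutes, default 0.2.
#' @return data.frame with columns `a_id`, `b_id`, `dmz_ppm`, `drt`.
#' @export
match_features <- function(a, b, mz_tol_ppm = 5, rt_tol = 0.2) {
  stopifnot(mz_tol_ppm > 0, rt_tol > 0)
  empty <- data.frame(a_id = character(0), b_id = character(0),
                      dmz_ppm = numeric(0), drt = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  cand <- do.call(rbind, lapply(seq_len(nrow(a)), function(i) {
    dmz <- ppm_error(b$mz, a$mz[i])
    drt <- b$rt_min - a$rt_min[i]
    j <- which(abs(dmz) <= mz_tol_ppm & abs(drt) <= rt_tol)
    if (!length(j)) return(NULL)
    data.frame(ai = i, bj = j, dmz_ppm = dmz[j], drt = drt[j])
  }))
  if (is.null(cand)) return(empty)
  cand <- cand[order(abs(cand$dmz_ppm), abs(cand$drt), cand$ai, cand$bj), ]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$ai[k]; j <- cand$bj[k]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(a_id = a$feature_id[cand$ai], b_id = b$feature_id[cand$bj],
             dmz_ppm = cand$dmz_ppm, drt = cand$drt,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Remove features attributable to the blank/control run
#'
#' A sample feature is removed when a matched control feature carries a
#' peak area greater than `threshold_fraction` of the sample feature's
#' area (default 0.01%). Sample features with no control match are always
#' retained.
#'
#' @param sample,control feature data.frames.
#' @param threshold_fraction area-ratio threshold, default `1e-4` (0.01%).
#' @param mz_tol_ppm,rt_tol matching tolerances, see [match_features()].
#' @return The retained subset of `sample`.
#' @export
blank_filter <- function(sample, control, threshold_fraction = 1e-4,
                         mz_tol_ppm = 5, rt_tol = 0.2) {
  if (is.null(control) || nrow(sample) == 0L || nrow(control) == 0L)
    return(sample)
  m <- match_features(sample, control, mz_tol_ppm, rt_tol)
  if (nrow(m) == 0L) return(sample)
  s_area <- sample$area[match(m$a_id, sample$feature_id)]
  c_area <- control$area[match(m$b_id, control$feature_id)]
  drop_ids <- m$a_id[c_area > threshold_fraction * s_area]
  sample[!sample$feature_id %in% drop_ids, , drop = FALSE]
}

#' Detect the 54Fe/56Fe isotope signature
#'
#' For each feature, looks for an isotopologue peak 1.99533 Da below the
#' monoisotopic (56Fe) m/z whose relative intensity falls inside the
#' natural-abundance window (theoretical 54Fe/56Fe ratio 0.0637). The A-2
#' partner is taken from the feature's isotopologue envelope when one is
#' supplied; otherwise a co-eluting feature in the table at the right
#' spacing is used, with the area ratio standing in for the intensity
#' ratio.
#'
#' @param features feature data.frame.
#' @param envelopes optional long-format data.frame
#'   (`feature_id`, `iso_mz`, `rel_intensity`) of isotopologue peaks; the
#'   monoisotopic peak has `rel_intensity` 1.
#' @param spacing_tol_da tolerance on the A-2 spacing in Da, default 0.003.
#' @param ratio_window allowed A-2/A intensity-ratio interval, default
#'   `c(0.02, 0.15)` (roughly a factor 2.5 around 0.0637, wide enough for
#'   counting noise, narrow enough to reject Cl/Br-type patterns).
#' @param rt_tol co-elution tolerance (min) for the table-based fallback.
#' @return data.frame with columns `feature_id`, `partner_mz`,
#'   `spacing_error_mda`, `abundance_ratio`.
#' @export
find_iron_pattern_hits <- function(features, envelopes = NULL,
                                   spacing_tol_da = 0.003,
                                   ratio_window = c(0.02, 0.15),
                                   rt_tol = 0.05) {
  k <- mass_constants()
  hits <- list()
  env_by_id <- if (!is.null(envelopes) && nrow(envelopes))
    split(envelopes, envelopes$feature_id) else list()
  for (i in seq_len(nrow(features))) {
    fid <- features$feature_id[i]
    mz <- features$mz[i]
    target <- mz - k$fe_spacing
    env <- env_by_id[[as.character(fid)]]
    if (!is.null(env) && nrow(env)) {
      d <- abs(env$iso_mz - target)
      j <- which.min(d)
      if (d[j] <= spacing_tol_da) {
        ratio <- env$rel_intensity[j]
        if (ratio >= ratio_window[1] && ratio <= ratio_window[2])
          hits[[length(hits) + 1L]] <- data.frame(
            feature_id = fid, partner_mz = env$iso_mz[j],
            spacing_error_mda = 1e3 * (mz - env$iso_mz[j] - k$fe_spacing),
            abundance_ratio = ratio, stringsAsFactors = FALSE)
      }
    } else {
      j <- which(abs(features$mz - target) <= spacing_tol_da &
                 abs(features$rt_min - features$rt_min[i]) <= rt_tol &
                 features$feature_id != fid)
      if (length(j)) {
        j <- j[which.min(abs(features$mz[j] - target))]
        ratio <- features$area[j] / features$area[i]
        if (ratio >= ratio_window[1] && ratio <= ratio_window[2])
          hits[[length(hits) + 1L]] <- data.frame(
            feature_id = fid, partner_mz = features$mz[j],
            spacing_error_mda = 1e3 * (mz - features$mz[j] - k$fe_spacing),
            abundance_ratio = ratio, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(feature_id = character(0), partner_mz = numeric(0),
                      spacing_error_mda = numeric(0),
                      abundance_ratio = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Pair apo siderophores with their ferric complexes by exact mass
#'
#' Enumerates feature pairs whose m/z difference equals the constant
#' ferric-complex offset 56Fe - 3 H = 52.91146 Da within tolerance and
#' whose retention times differ by at most `rt_window` (iron complexes
#' elute at shifted but nearby retention times). Singly protonated ions
#' are assumed on both sides.
#'
#' @param features feature data.frame.
#' @param mz_tol_da tolerance on the mass difference (Da), default 0.003.
#' @param rt_window maximum |RT(apo) - RT(holo)| in minutes, default 2.
#' @return data.frame with columns `apo_feature_id`, `holo_feature_id`,
#'   `mass_error_ppm` (of the observed difference vs 52.91146, relative to
#'   the holo m/z), `rt_shift` (holo - apo, min), `apo_fraction`
#'   (area(apo) / (area(apo) + area(holo))); sorted by |mass error|.
#' @export
pair_apo_holo <- function(features, mz_tol_da = 0.003, rt_window = 2.0) {
  shift <- mass_constants()$holo_shift
  out <- list()
  for (i in seq_len(nrow(features))) {
    d <- features$mz - features$mz[i] - shift
    j <- which(abs(d) <= mz_tol_da &
               abs(features$rt_min - features$rt_min[i]) <= rt_window)
    for (jj in j) {
      apo_a <- features$area[i]; holo_a <- features$area[jj]
      out[[length(out) + 1L]] <- data.frame(
        apo_feature_id = features$feature_id[i],
        holo_feature_id = features$feature_id[jj],
        mass_error_ppm = 1e6 * d[jj] / features$mz[jj],
        rt_shift = features$rt_min[jj] - features$rt_min[i],
        apo_fraction = apo_a / (apo_a + holo_a),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(apo_feature_id = character(0),
                      holo_feature_id = character(0),
                      mass_error_ppm = numeric(0), rt_shift = numeric(0),
                      apo_fraction = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(abs(res$mass_error_ppm), res$apo_feature_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}
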