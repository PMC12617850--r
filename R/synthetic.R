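#' Configuration of a synthetic LC-MS siderophore scenario
#'
#' Defines the study conditions emulated by [generate_scenario()]: five
#' hydroxamate siderophore families around the base neutral formula
#' C33H62N6O13, related by CH2 and O increments (offsets
#' `{0, -CH2, +O, +CH2+O, +2CH2+O}` relative to the base), each present as
#' a minor apo [M+H]+ feature and a major ferric-complex
#' [M-3H+Fe+H]+ feature with natural-abundance iron isotopologue
#' envelopes and a shifted retention time; plus decoy metabolites (plain
#' organics, chlorine-pattern decoys whose isotope spacing mimics
#' 54Fe/56Fe but whose ratio does not, and correct-spacing/wrong-ratio
#' decoys), blank-shared features reproduced in the control run, and the
#' ubiquitous MS/MS contaminant ion at m/z 202.080.
#'
#' Noise model: the m/z error combines a run-level calibration bias with
#' per-feature jitter (about 1 ppm total); peak areas are log-normal;
#' isotopologue intensity ratios and MS/MS intensities carry relative
#' Gaussian noise.
#'
#' @param seed integer RNG seed; a fixed seed gives identical output.
#' @param base_formula neutral formula of the most abundant siderophore.
#' @param offsets data.frame with integer columns `ch2` and `o`; one row
#'   per family, in CH2/O increments relative to `base_formula`.
#' @param apo_fraction fraction of each family's total area carried by
#'   the apo species (< 0.5: the ferric complex is the major fraction).
#' @param n_decoys_plain,n_decoys_cl,n_decoys_ratio decoy counts.
#' @param blank_shared number of plain decoys also present in the control
#'   run at `blank_area_ratio` of their sample area.
#' @param blank_area_ratio control/sample area ratio of blank-shared
#'   features (well above the 0.01% removal threshold).
#' @param mz_bias_ppm,mz_jitter_ppm run-level and per-feature components
#'   of the m/z error (standard deviations, ppm).
#' @param area_sigma log-normal sigma of the peak areas.
#' @param envelope_noise relative sd of isotopologue intensity ratios.
#' @param msms_noise relative sd of MS/MS peak intensities.
#' @param n_noise_peaks low-intensity random peaks added per MS/MS
#'   spectrum.
#' @param contaminant add the m/z 202.080 contaminant ion to every
#'   spectrum (default `TRUE`).
#' @param rt_range chromatographic window (min) for feature placement,
#'   default `c(1.5, 8)` (the gradient window).
#' @param holo_rt_shift magnitude range (min) of the ferric-complex RT
#'   shift, default `c(0.2, 0.5)`, random sign.
#' @param scan_range acquisition m/z range.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1,
                            base_formula = "C33H62N6O13",
                            offsets = data.frame(ch2 = c(0L, -1L, 0L, 1L, 2L),
                                                 o = c(0L, 0L, 1L, 1L, 1L)),
                            apo_fraction = 0.25,
                            n_decoys_plain = 16, n_decoys_cl = 4,
                            n_decoys_ratio = 4,
                            blank_shared = 4, blank_area_ratio = 0.5,
                            mz_bias_ppm = 0.8, mz_jitter_ppm = 0.3,
                            area_sigma = 0.1, envelope_noise = 0.05,
                            msms_noise = 0.05, n_noise_peaks = 3,
                            contaminant = TRUE,
                            rt_range = c(1.5, 8),
                            holo_rt_shift = c(0.2, 0.5),
                            scan_range = c(80, 1500)) {
  cfg <- structure(as.list(environment()), class = "scenario_config")
  base <- parse_formula(cfg$base_formula)
  for (i in seq_len(nrow(cfg$offsets))) {
    f <- offset_formula(base, cfg$offsets$ch2[i], cfg$offsets$o[i])
    mzs <- c(protonated_mz(monoisotopic_mass(f)),
             ferric_complex_mz(monoisotopic_mass(f)))
    if (any(mzs < scan_range[1]) || any(mzs > scan_range[2]))
      stop("planted family ", i, " falls outside the scan range")
  }
  if (cfg$apo_fraction <= 0 || cfg$apo_fraction >= 1)
    stop("apo_fraction must be in (0, 1)")
  cfg
}

offset_formula <- function(base, ch2, o) {
  v <- c(unclass(base))
  v["C"] <- v["C"] + ch2
  v["H"] <- v["H"] + 2L * ch2
  v["O"] <- (if ("O" %in% names(v)) v[["O"]] else 0L) + o
  if (any(v < 0)) stop("offset drives an element count negative")
  as_chem_formula(v)
}

#' Simulate an isotopologue envelope for a formula
#'
#' Produces the monoisotopic peak, the 13C A+1 peak (binomial
#' approximation, n_C x 0.0107) and, when the formula contains iron, the
#' diagnostic 54Fe A-2 peak 1.99533 Da below the monoisotopic mass at the
#' natural 54Fe/56Fe abundance ratio (0.0637). Intensities are relative
#' to the monoisotopic peak; no noise is applied here.
#'
#' @param f formula string or `chem_formula` (the ionic species whose
#'   envelope is observed; only spacings and ratios matter).
#' @param include_fe emit the A-2 iron peak; defaults to whether the
#'   formula contains Fe.
#' @param mz0 m/z of the monoisotopic peak; defaults to the formula's
#'   monoisotopic mass.
#' @return matrix with columns `mz`, `rel_intensity`, rows sorted by m/z.
#' @examples
#' simulate_isotope_envelope("C33H59N6O13Fe")
#' @export
simulate_isotope_envelope <- function(f, include_fe = NULL, mz0 = NULL) {
  f <- coerce_formula(f)
  k <- mass_constants()
  if (is.null(mz0)) mz0 <- monoisotopic_mass(f)
  n_fe <- if ("Fe" %in% names(f)) f[["Fe"]] else 0L
  n_c <- if ("C" %in% names(f)) f[["C"]] else 0L
  if (is.null(include_fe)) include_fe <- n_fe > 0L
  env <- cbind(mz = mz0, rel_intensity = 1)
  if (n_c > 0L)
    env <- rbind(env, cbind(mz = mz0 + 1.0033548, # 13C - 12C
                            rel_intensity = n_c * k$c13_abundance))
  if (include_fe && n_fe > 0L)
    env <- rbind(env, cbind(mz = mz0 - k$fe_spacing,
                            rel_intensity = k$fe_ratio))
  env[order(env[, "mz"]), , drop = FALSE]
}

#' Simulate a hydroxamate siderophore MS/MS spectrum
#'
#' Emits the building-block fragment ions of an N5-hydroxyornithine /
#' N-acyl tris-hydroxamate (protonated fragments near m/z 86.060,
#' 115.075, 131.082, 157.061) and the complementary ions at precursor
#' minus the corresponding residue losses (114.068, 130.074, 158.069),
#' with relative Gaussian intensity noise, optional uniform noise peaks
#' and the optional contaminant ion at m/z 202.080. With zero noise and
#' no extras the peak list is a deterministic template. Uses the current
#' RNG state; seed upstream for reproducibility.
#'
#' @param precursor_mz precursor ion m/z ([M+H]+ of the apo species).
#' @param spectrum_id,feature_id,rt identifiers and retention time.
#' @param intensity_noise relative sd of peak intensities.
#' @param n_noise_peaks number of low-intensity random peaks.
#' @param contaminant add the 202.080 contaminant peak.
#' @return a [fragment_spectrum()].
#' @export
simulate_msms <- function(precursor_mz, spectrum_id = "msms",
                          feature_id = NA_character_, rt = NA_real_,
                          intensity_noise = 0, n_noise_peaks = 0,
                          contaminant = FALSE) {
  lib <- building_block_library()
  frag <- stats::setNames(lib$fragment_mz, lib$name)
  loss <- stats::setNames(lib$loss_mass, lib$name)
  mz <- c(frag[["C4H7NO"]], frag[["hexanoyl-C6H10O2"]],
          frag[["N5-hydroxyornithine"]],
          frag[["N5-formyl-N5-hydroxyornithine"]],
          precursor_mz - loss[["hexanoyl-C6H10O2"]],
          precursor_mz - loss[["N5-hydroxyornithine"]],
          precursor_mz - loss[["N5-formyl-N5-hydroxyornithine"]])
  int <- c(900, 400, 500, 300, 450, 350, 250)
  if (intensity_noise > 0)
    int <- int * pmax(0.05, 1 + stats::rnorm(length(int), 0, intensity_noise))
  if (contaminant) { mz <- c(mz, 202.080); int <- c(int, 300) }
  if (n_noise_peaks > 0) {
    mz <- c(mz, stats::runif(n_noise_peaks, 80, precursor_mz - 5))
    int <- c(int, stats::runif(n_noise_peaks, 5, 50))
  }
  fragment_spectrum(spectrum_id, precursor_mz, cbind(mz, int),
                    precursor_rt = rt, feature_id = feature_id)
}

#' Generate a synthetic LC-MS scenario with ground truth
#'
#' Builds the complete in-memory dataset described by a
#' [scenario_config()]: a sample MS1 feature table, a blank/control
#' feature table, isotopologue envelopes, MS/MS spectra and a ground-truth
#' table assigning every feature a role (`apo`, `holo`, `decoy`,
#' `blank_shared`) and family. The same seed always produces the same
#' dataset.
#'
#' @param cfg a [scenario_config()].
#' @return list of class `lcms_scenario` with elements `sample`,
#'   `control` (feature data.frames), `envelopes` (long-format
#'   isotopologue table), `spectra` (list of [fragment_spectrum()]),
#'   `truth` (data.frame: `feature_id`, `role`, `family`, `formula`) and
#'   `config`.
#' @examples
#' scn <- generate_scenario(scenario_config(seed = 7))
#' table(scn$truth$role)
#' @export
generate_scenario <- function(cfg = scenario_config()) {
  stopifnot(inherits(cfg, "scenario_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  k <- mass_constants()
  base <- parse_formula(cfg$base_formula)
  n_fam <- nrow(cfg$offsets)
  bias <- stats::rnorm(1, 0, cfg$mz_bias_ppm)     # run-level calibration
  jitter <- function(mz) mz * (1 + (bias + stats::rnorm(length(mz), 0, cfg$mz_jitter_ppm)) * 1e-6)

  feats <- list(); envs <- list(); truth <- list(); spectra <- list()
  add_feature <- function(id, mz, rt, area, role, family, formula) {
    feats[[length(feats) + 1L]] <<- data.frame(
      feature_id = id, mz = mz, rt_min = rt, area = area,
      polarity = "positive", stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      feature_id = id, role = role, family = family, formula = formula,
      stringsAsFactors = FALSE)
  }
  add_envelope <- function(id, env) {
    envs[[length(envs) + 1L]] <<- data.frame(
      feature_id = id, iso_mz = env[, "mz"],
      rel_intensity = env[, "rel_intensity"], stringsAsFactors = FALSE)
  }

  ## --- siderophore families -------------------------------------------
  fam_area <- c(1e8, rep(2e7, n_fam - 1L))  # base family most abundant
  apo_rts <- stats::runif(n_fam, cfg$rt_range[1], cfg$rt_range[2] - 0.6)
  for (i in seq_len(n_fam)) {
    f_apo <- offset_formula(base, cfg$offsets$ch2[i], cfg$offsets$o[i])
    m <- monoisotopic_mass(f_apo)
    apo_mz_true <- protonated_mz(m)
    holo_mz_true <- ferric_complex_mz(m)
    total <- fam_area[i] * stats::rlnorm(1, 0, cfg$area_sigma)
    rt_apo <- apo_rts[i]
    rt_holo <- rt_apo + sample(c(-1, 1), 1) *
      stats::runif(1, cfg$holo_rt_shift[1], cfg$holo_rt_shift[2])
    apo_id <- sprintf("apo_%02d", i); holo_id <- sprintf("holo_%02d", i)
    add_feature(apo_id, jitter(apo_mz_true), rt_apo,
                total * cfg$apo_fraction, "apo", i, format_formula(f_apo))
    add_feature(holo_id, jitter(holo_mz_true), rt_holo,
                total * (1 - cfg$apo_fraction), "holo", i,
                format_formula(f_apo))
    ## envelopes: apo has 13C only; holo adds the 54Fe A-2 peak
    env_apo <- simulate_isotope_envelope(f_apo, mz0 = jitter(apo_mz_true))
    holo_counts <- c(unclass(f_apo)); holo_counts["H"] <- holo_counts["H"] - 3L
    holo_counts["Fe"] <- 1L
    env_holo <- simulate_isotope_envelope(as_chem_formula(holo_counts),
                                          mz0 = jitter(holo_mz_true))
    noisy <- function(env) {
      i2 <- env[, "rel_intensity"] != 1
      env[i2, "rel_intensity"] <- env[i2, "rel_intensity"] *
        pmax(0.1, 1 + stats::rnorm(sum(i2), 0, cfg$envelope_noise))
      env
    }
    add_envelope(apo_id, noisy(env_apo))
    add_envelope(holo_id, noisy(env_holo))
    spectra[[length(spectra) + 1L]] <- simulate_msms(
      jitter(apo_mz_true), spectrum_id = paste0("msms_", apo_id),
      feature_id = apo_id, rt = rt_apo,
      intensity_noise = cfg$msms_noise, n_noise_peaks = cfg$n_noise_peaks,
      contaminant = cfg$contaminant)
  }

  ## --- decoys ----------------------------------------------------------
  planted_mz <- vapply(feats, function(f) f$mz, numeric(1))
  draw_decoy_mz <- function() {
    repeat {
      mz <- stats::runif(1, 120, 900)
      d <- abs(planted_mz - mz)
      ## avoid accidental apo/holo pairings or near-duplicate m/z
      if (all(abs(d - k$holo_shift) > 0.02) && all(d > 0.05)) {
        planted_mz <<- c(planted_mz, mz)
        return(mz)
      }
    }
  }
  decoy_roles <- c(rep("plain", cfg$n_decoys_plain),
                   rep("cl_pattern", cfg$n_decoys_cl),
                   rep("wrong_ratio", cfg$n_decoys_ratio))
  blank_ids <- character(0)
  for (d in seq_along(decoy_roles)) {
    id <- sprintf("decoy_%02d", d)
    mz <- draw_decoy_mz()
    rt <- stats::runif(1, cfg$rt_range[1], cfg$rt_range[2])
    area <- stats::rlnorm(1, log(5e6), 0.5)
    role <- if (decoy_roles[d] == "plain" && length(blank_ids) < cfg$blank_shared)
      "blank_shared" else "decoy"
    if (role == "blank_shared") blank_ids <- c(blank_ids, id)
    add_feature(id, mz, rt, area, role, NA_integer_, NA_character_)
    n_c <- max(1L, round(mz / 20))
    env <- cbind(mz = c(mz, mz + 1.0033548),
                 rel_intensity = c(1, n_c * k$c13_abundance))
    if (decoy_roles[d] == "cl_pattern") {
      ## feature is the 37Cl isotopologue: partner 1.99705 below, ratio ~3.1
      env <- rbind(env, cbind(mz = mz - 1.99705, rel_intensity = 3.13))
    } else if (decoy_roles[d] == "wrong_ratio") {
      env <- rbind(env, cbind(mz = mz - k$fe_spacing, rel_intensity = 0.5))
    }
    add_envelope(id, env[order(env[, "mz"]), , drop = FALSE])
    if (decoy_roles[d] == "plain") {
      n_pk <- sample(6:10, 1)
      pk <- cbind(stats::runif(n_pk, 80, max(90, mz - 10)),
                  stats::runif(n_pk, 50, 1000))
      spectra[[length(spectra) + 1L]] <- fragment_spectrum(
        paste0("msms_", id), mz, pk, precursor_rt = rt, feature_id = id)
      if (cfg$contaminant) {
        s <- spectra[[length(spectra)]]
        s$peaks <- rbind(s$peaks, c(202.080, 300))
        s$peaks <- s$peaks[order(s$peaks[, 1]), , drop = FALSE]
        spectra[[length(spectra)]] <- s
      }
    }
  }

  sample_df <- do.call(rbind, feats)
  truth_df <- do.call(rbind, truth)

  ## --- control run: blank-shared features plus its own background ------
  ctrl <- list()
  for (id in blank_ids) {
    row <- sample_df[sample_df$feature_id == id, ]
    ctrl[[length(ctrl) + 1L]] <- data.frame(
      feature_id = paste0("ctrl_", id),
      mz = row$mz * (1 + stats::rnorm(1, 0, 0.5) * 1e-6),
      rt_min = row$rt_min + stats::rnorm(1, 0, 0.02),
      area = row$area * cfg$blank_area_ratio,
      polarity = "positive", stringsAsFactors = FALSE)
  }
  for (b in 1:5) {
    ctrl[[length(ctrl) + 1L]] <- data.frame(
      feature_id = sprintf("ctrl_bg_%02d", b),
      mz = draw_decoy_mz(),
      rt_min = stats::runif(1, cfg$rt_range[1], cfg$rt_range[2]),
      area = stats::rlnorm(1, log(1e6), 0.5),
      polarity = "positive", stringsAsFactors = FALSE)
  }
  control_df <- do.call(rbind, ctrl)

  structure(list(sample = sample_df, control = control_df,
                 envelopes = do.call(rbind, envs), spectra = spectra,
                 truth = truth_df, config = cfg),
            class = "lcms_scenario")
}

#' @export
print.lcms_scenario <- function(x, ...) {
  cat("Synthetic LC-MS scenario (seed ", x$config$seed, "): ",
      nrow(x$sample), " sample features, ", nrow(x$control),
      " control features, ", length(x$spectra), " MS/MS spectra\n", sep = "")
  print(table(x$truth$role))
  invisible(x)
}

#' Write a synthetic scenario to disk
#'
#' Emits `sample.csv`, `control.csv`, `envelopes.csv` (long format),
#' `spectra.mgf` and `truth.json` into a directory.
#'
#' @param scn an `lcms_scenario` from [generate_scenario()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  stopifnot(inherits(scn, "lcms_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_features(scn$sample, file.path(dir, "sample.csv"))
  write_features(scn$control, file.path(dir, "control.csv"))
  utils::write.csv(scn$envelopes, file.path(dir, "envelopes.csv"),
                   row.names = FALSE, quote = FALSE)
  write_mgf(scn$spectra, file.path(dir, "spectra.mgf"))
  jsonlite::write_json(scn$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
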