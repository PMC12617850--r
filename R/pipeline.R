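#' Pipeline configuration
#'
#' All thresholds of the screening/networking pipeline in one place, with
#' the processing defaults of the study design this package implements:
#' fragment tolerance 5 ppm or 0.003 Da (whichever larger), cosine
#' threshold 0.7, minimum 5 matched fragment ions, 10-neighbour cap,
#' top-5 ions per 50 Da window, 0.1% intensity floor, blank threshold
#' 0.01%, contaminant ion m/z 202.080, scan range m/z 80-1500.
#'
#' @param seed RNG seed used by the simulate stage.
#' @param simulate generate the input data with [generate_scenario()]
#'   (default `TRUE`); otherwise `sample_csv` (and optionally
#'   `control_csv`, `envelopes_csv`, `mgf`) are read.
#' @param sample_csv,control_csv,envelopes_csv,mgf input paths when
#'   `simulate = FALSE`.
#' @param tol_ppm,tol_da fragment/feature mass tolerance.
#' @param cosine_min,min_matched,max_neighbors molecular-network
#'   thresholds.
#' @param top_k,window_da,min_rel_intensity MS/MS peak-filter parameters.
#' @param blank_fraction blank-removal area-ratio threshold.
#' @param contaminant_mz contaminant ion removed from all spectra.
#' @param scan_range acquisition m/z range.
#' @param require_apo,ratio_window,rt_pair_window,rt_match_tol screen
#'   parameters, see [screen_config()].
#' @param min_blocks distinct building-block threshold for the
#'   hydroxamate flag.
#' @param scenario a [scenario_config()] for the simulate stage; built
#'   from `seed` when `NULL`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, simulate = TRUE,
                            sample_csv = NULL, control_csv = NULL,
                            envelopes_csv = NULL, mgf = NULL,
                            tol_ppm = 5, tol_da = 0.003,
                            cosine_min = 0.7, min_matched = 5,
                            max_neighbors = 10,
                            top_k = 5, window_da = 50,
                            min_rel_intensity = 0.001,
                            blank_fraction = 1e-4,
                            contaminant_mz = 202.080,
                            scan_range = c(80, 1500),
                            require_apo = TRUE,
                            ratio_window = c(0.02, 0.15),
                            rt_pair_window = 2.0, rt_match_tol = 0.2,
                            min_blocks = 2, scenario = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

pipeline_defaults <- function() pipeline_config()

#' Validate a pipeline configuration
#'
#' Checks thresholds for admissible ranges and reports, as warnings, any
#' parameter that deviates from the package's standard processing
#' defaults.
#'
#' @param cfg a [pipeline_config()].
#' @return list with character vectors `errors` and `warnings`; an empty
#'   `errors` vector means the configuration is usable.
#' @export
validate_config <- function(cfg) {
  errors <- character(0); warnings <- character(0)
  bad <- function(msg) errors <<- c(errors, msg)
  if (!is.numeric(cfg$cosine_min) || cfg$cosine_min < 0 || cfg$cosine_min > 1)
    bad("cosine_min must lie in [0, 1]")
  if (!is.numeric(cfg$min_matched) || cfg$min_matched < 1)
    bad("min_matched must be >= 1")
  if (!is.numeric(cfg$max_neighbors) || cfg$max_neighbors < 1)
    bad("max_neighbors must be >= 1")
  if (cfg$tol_ppm <= 0 || cfg$tol_da <= 0)
    bad("mass tolerances must be positive")
  if (cfg$top_k < 1 || cfg$window_da <= 0)
    bad("peak-filter parameters must be positive")
  if (cfg$min_rel_intensity < 0 || cfg$min_rel_intensity >= 1)
    bad("min_rel_intensity must lie in [0, 1)")
  if (cfg$blank_fraction < 0 || cfg$blank_fraction >= 1)
    bad("blank_fraction must lie in [0, 1)")
  if (length(cfg$scan_range) != 2L || cfg$scan_range[1] >= cfg$scan_range[2])
    bad("scan_range must be an increasing length-2 range")
  if (!cfg$simulate && is.null(cfg$sample_csv))
    bad("sample_csv is required when simulate = FALSE")
  def <- pipeline_defaults()
  for (p in c("tol_ppm", "tol_da", "cosine_min", "min_matched",
              "max_neighbors", "top_k", "window_da", "min_rel_intensity",
              "blank_fraction", "contaminant_mz")) {
    if (!isTRUE(all.equal(cfg[[p]], def[[p]])))
      warnings <- c(warnings, paste0("parameter '", p,
                                     "' overrides the standard default (",
                                     def[[p]], ")"))
  }
  list(errors = errors, warnings = warnings)
}

#' Run the siderophore discovery pipeline
#'
#' Executes the stages in order: (optional) simulate, blank subtraction,
#' MS1 siderophore screen (iron isotope pattern + apo/ferric-complex mass
#' pairing + formula decomposition), MS/MS hygiene (contaminant removal,
#' windowed top-k filtering), hydroxamate building-block annotation of
#' candidate spectra, and feature-based molecular networking. Output
#' files are written when `out_dir` is given: `candidates.csv`,
#' `spectra_filtered.mgf`, `network.graphml`, `network_nodes.csv`,
#' `network_edges.csv` and `report.json`.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return object of class `run_report`: stage counts, the
#'   `siderophore_screen` object, the candidate table (with MS/MS evidence
#'   columns), the `molecular_network`, the parameter echo and the seed.
#' @examples
#' rep <- run_pipeline(pipeline_config(seed = 1))
#' rep
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  chk <- validate_config(cfg)
  if (length(chk$errors))
    stop("invalid configuration:\n  ", paste(chk$errors, collapse = "\n  "))
  for (w in chk$warnings) message("note: ", w)

  ## stage 1: inputs
  if (cfg$simulate) {
    scn_cfg <- if (is.null(cfg$scenario)) scenario_config(seed = cfg$seed)
               else cfg$scenario
    scn <- generate_scenario(scn_cfg)
    sample <- scn$sample; control <- scn$control
    envelopes <- scn$envelopes; spectra <- scn$spectra
  } else {
    sample <- read_features(cfg$sample_csv, cfg$scan_range)
    control <- if (!is.null(cfg$control_csv))
      read_features(cfg$control_csv, cfg$scan_range) else NULL
    envelopes <- if (!is.null(cfg$envelopes_csv))
      utils::read.csv(cfg$envelopes_csv, stringsAsFactors = FALSE) else NULL
    spectra <- if (!is.null(cfg$mgf)) read_mgf(cfg$mgf) else list()
  }

  ## stage 2+3: blank subtraction and MS1 screen
  scr <- screen_siderophores(sample, control, envelopes,
                             screen_config(
                               blank_fraction = cfg$blank_fraction,
                               mz_tol_ppm = cfg$tol_ppm,
                               mz_tol_da = cfg$tol_da,
                               rt_match_tol = cfg$rt_match_tol,
                               rt_pair_window = cfg$rt_pair_window,
                               ratio_window = cfg$ratio_window,
                               require_apo = cfg$require_apo,
                               scan_range = cfg$scan_range))
  retained <- blank_filter(sample, control, cfg$blank_fraction,
                           cfg$tol_ppm, cfg$rt_match_tol)

  ## stage 4: MS/MS hygiene, restricted to surviving features
  spectra <- Filter(function(s)
    is.na(s$feature_id) || s$feature_id %in% retained$feature_id, spectra)
  spectra <- lapply(spectra, function(s)
    filter_peaks(remove_contaminant(s, cfg$contaminant_mz, cfg$tol_da),
                 cfg$top_k, cfg$window_da, cfg$min_rel_intensity))

  ## stage 5: hydroxamate annotation of candidate spectra
  lib <- building_block_library()
  candidates <- scr$candidates
  candidates$msms_blocks <- rep(0L, nrow(candidates))
  candidates$hydroxamate_consistent <- rep(FALSE, nrow(candidates))
  spec_by_feature <- stats::setNames(spectra, vapply(spectra, function(s)
    s$feature_id, character(1)))
  for (i in seq_len(nrow(candidates))) {
    fid <- candidates$apo_feature_id[i]
    s <- if (!is.na(fid)) spec_by_feature[[fid]] else NULL
    if (is.null(s)) next
    ev <- score_hydroxamate_evidence(s, min_blocks = cfg$min_blocks,
                                     library = lib)
    candidates$msms_blocks[i] <- ev$n_blocks
    candidates$hydroxamate_consistent[i] <- ev$consistent
  }

  ## stage 6: molecular network
  net <- build_network(spectra, cfg$cosine_min, cfg$min_matched,
                       cfg$max_neighbors, cfg$tol_ppm, cfg$tol_da)
  net$nodes$area <- retained$area[match(net$nodes$feature_id,
                                        retained$feature_id)]
  net$nodes$siderophore <- net$nodes$feature_id %in%
    c(candidates$apo_feature_id, candidates$holo_feature_id)

  report <- structure(list(
    counts = c(features_in = nrow(sample),
               features_after_blank = nrow(retained),
               iron_hits = scr$counts[["iron_hits"]],
               apo_holo_pairs = scr$counts[["apo_holo_pairs"]],
               candidates = nrow(candidates),
               spectra = length(spectra),
               network_nodes = nrow(net$nodes),
               network_edges = nrow(net$edges)),
    candidates = candidates, screen = scr, network = net,
    parameters = unclass(cfg)[!vapply(cfg, is.null, logical(1))],
    seed = cfg$seed,
    version = as.character(utils::packageVersion("sideroscan"))),
    class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(candidates, file.path(out_dir, "candidates.csv"),
                     row.names = FALSE)
    write_mgf(spectra, file.path(out_dir, "spectra_filtered.mgf"))
    export_graphml(net, file.path(out_dir, "network.graphml"))
    export_network_tables(net, file.path(out_dir, "network_nodes.csv"),
                          file.path(out_dir, "network_edges.csv"))
    jsonlite::write_json(
      list(counts = as.list(report$counts),
           candidates = candidates,
           parameters = report$parameters[!vapply(report$parameters,
                                                  is.list, logical(1))],
           seed = cfg$seed, version = report$version),
      file.path(out_dir, "report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Siderophore pipeline report (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$counts))
    cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  if (nrow(x$candidates)) {
    cat("Candidates:\n")
    print(x$candidates[, c("apo_mz", "holo_mz", "top_formula",
                           "msms_blocks", "hydroxamate_consistent")])
  }
  invisible(x)
}

#' Build a pipeline configuration from a YAML file
#'
#' Scalar fields of the YAML map directly onto [pipeline_config()]
#' arguments; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  y <- lapply(y, function(v) if (is.list(v)) unlist(v) else v)
  do.call(pipeline_config, y)
}
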