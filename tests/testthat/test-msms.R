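spec_of <- function(mz, int, precursor = 751.4448, id = "s")
  fragment_spectrum(id, precursor, cbind(mz, int))

test_that("MGF I/O round-trips spectra", {
  scn <- generate_scenario(scenario_config(seed = 4))
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(scn$spectra, path)
  back <- read_mgf(path)
  expect_identical(length(back), length(scn$spectra))
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$feature_id, scn$spectra[[i]]$feature_id)
    expect_equal(back[[i]]$precursor_mz, scn$spectra[[i]]$precursor_mz,
                 tolerance = 1e-5)
    expect_equal(back[[i]]$peaks[, "mz"], scn$spectra[[i]]$peaks[, "mz"],
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
  expect_error(read_mgf(withr::local_tempfile(lines = "BEGIN IONS")),
               "unbalanced")
})

test_that("contaminant removal drops only peaks near 202.080", {
  s <- spec_of(c(150.0, 202.0800, 202.0900, 400.0), c(10, 50, 20, 100))
  out <- remove_contaminant(s)
  expect_identical(out$peaks[, "mz"], c(150.0, 202.09, 400.0),
                   ignore_attr = TRUE)
  s2 <- spec_of(c(150.0, 400.0), c(10, 100))
  expect_identical(remove_contaminant(s2)$peaks, s2$peaks)
})

test_that("peak filtering keeps top-5 per 50 Da window and applies the 0.1% floor", {
  ## 6 peaks inside one 50 Da window with distinct intensities -> 5 survive
  s <- spec_of(200 + 0:5 * 4, c(60, 50, 40, 30, 20, 10) * 10)
  out <- filter_peaks(s)
  expect_identical(nrow(out$peaks), 5L)
  expect_false((200 + 5 * 4) %in% out$peaks[, "mz"])  # weakest peak dropped
  ## peak at 0.05% of base peak removed; 5 isolated peaks untouched
  s2 <- spec_of(c(100, 200, 300, 400, 500), c(1000, 0.5, 900, 800, 700))
  out2 <- filter_peaks(s2)
  expect_identical(out2$peaks[, "mz"], c(100, 300, 400, 500),
                   ignore_attr = TRUE)
  s3 <- spec_of(c(100, 200, 300), c(10, 20, 30))
  expect_identical(filter_peaks(s3)$peaks, s3$peaks)
})

test_that("peak filtering is idempotent and commutes with contaminant removal", {
  set.seed(42)
  for (rep in 1:10) {
    s <- spec_of(sort(runif(40, 80, 700)), runif(40, 0.5, 1000))
    once <- filter_peaks(s)
    expect_identical(filter_peaks(once)$peaks, once$peaks)
  }
  ## fixture where the contaminant is not the base peak and is isolated
  s <- spec_of(c(120, 202.0800, 310, 320, 330, 340, 350, 360),
               c(500, 300, 400, 350, 250, 200, 150, 100))
  ab <- filter_peaks(remove_contaminant(s))
  ba <- remove_contaminant(filter_peaks(s))
  expect_identical(ab$peaks, ba$peaks)
})

test_that("library masses agree with the printed fragment and loss values", {
  lib <- building_block_library()
  printed <- rbind(
    c("N5-hydroxyornithine", "fragment_mz", 131.0816),
    c("N5-hydroxyornithine", "loss_mass", 130.0731),
    c("N5-formyl-N5-hydroxyornithine", "fragment_mz", 157.0609),
    c("N5-formyl-N5-hydroxyornithine", "loss_mass", 158.0686),
    c("hexanoyl-C6H10O2", "fragment_mz", 115.0759),
    c("hexanoyl-C6H10O2", "loss_mass", 114.0681),
    c("C4H7NO", "fragment_mz", 86.0601))
  for (i in seq_len(nrow(printed))) {
    theory <- lib[lib$name == printed[i, 1], printed[i, 2]]
    expect_lt(abs(theory - as.numeric(printed[i, 3])), 2e-3)
  }
  ## internal consistency: ion = formula + proton, loss = formula mass
  expect_equal(lib$fragment_mz,
               vapply(lib$fragment_formula, protonated_mz, numeric(1)),
               tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(lib$loss_mass,
               vapply(lib$loss_formula, monoisotopic_mass, numeric(1)),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("annotation matches fragments and neutral losses within tolerance", {
  hits <- annotate_spectrum(spec_of(131.0815, 100))
  expect_true(any(hits$kind == "fragment" &
                    hits$block == "N5-hydroxyornithine"))
  expect_true(all(abs(hits$error_ppm[hits$kind == "fragment"]) <= 25))
  ## neutral loss of C6H10O2 from the precursor
  hits2 <- annotate_spectrum(spec_of(751.4450 - 114.0681, 100,
                                     precursor = 751.4450))
  expect_true(any(hits2$kind == "neutral_loss" &
                    hits2$block == "hexanoyl-C6H10O2"))
  expect_identical(nrow(annotate_spectrum(spec_of(numeric(0), numeric(0)))),
                   0L)
  ## far-off peak: no hits
  expect_identical(nrow(annotate_spectrum(spec_of(500.5, 100))), 0L)
})

test_that("hydroxamate evidence flags candidates with >= 2 distinct blocks", {
  s <- spec_of(c(86.0600, 637.3767), c(100, 50))  # C4H7NO + C6H10O2 loss
  ev <- score_hydroxamate_evidence(s)
  expect_true(ev$consistent)
  expect_gte(ev$n_blocks, 2)
  ev0 <- score_hydroxamate_evidence(spec_of(500.5, 100))
  expect_false(ev0$consistent)
  expect_identical(ev0$n_blocks, 0L)
  expect_equal(ev0$unexplained_major_peaks, 500.5)
  ## a full synthetic hydroxamate spectrum recovers all planted blocks
  sim <- simulate_msms(751.4448, contaminant = FALSE)
  evs <- score_hydroxamate_evidence(sim)
  expect_true(evs$consistent)
  expect_identical(sort(evs$blocks), sort(building_block_library()$name))
})
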