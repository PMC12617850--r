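toy_features <- function(mz, rt, area, ids = sprintf("f%02d", seq_along(mz))) {
  data.frame(feature_id = ids, mz = mz, rt_min = rt, area = area,
             polarity = "positive", stringsAsFactors = FALSE)
}

test_that("feature matching is greedy, one-to-one and tolerance-bound", {
  a <- toy_features(c(200.1, 350.2, 500.3), c(2, 3, 4), c(1e6, 2e6, 3e6))
  expect_identical(nrow(match_features(a, a)), 3L)
  b <- a; b$mz <- b$mz * (1 + 3e-6)      # +3 ppm
  m <- match_features(a, b, mz_tol_ppm = 5)
  expect_identical(nrow(m), 3L)
  expect_identical(m$a_id[order(m$a_id)], m$b_id[order(m$b_id)])
  b$mz <- a$mz * (1 + 20e-6)             # +20 ppm
  expect_identical(nrow(match_features(a, b, mz_tol_ppm = 5)), 0L)
  ## each feature matched at most once even with near-duplicates
  b2 <- rbind(a, within(a, feature_id <- paste0(feature_id, "_dup")))
  m2 <- match_features(a, b2)
  expect_identical(nrow(m2), 3L)
  expect_false(anyDuplicated(m2$b_id) > 0)
})

test_that("blank filter implements the 0.01% area rule", {
  s <- toy_features(c(200.1, 300.2, 400.3), c(2, 3, 4), c(1e8, 1e8, 1e8))
  ctl <- toy_features(c(200.1, 300.2), c(2, 3), c(0.0002 * 1e8, 0.00005 * 1e8),
                      ids = c("c1", "c2"))
  kept <- blank_filter(s, ctl, threshold_fraction = 1e-4)
  expect_identical(kept$feature_id, c("f02", "f03"))  # 0.02% removed, 0.005% kept
  ## no control partner -> always retained
  expect_identical(blank_filter(s, ctl[0, ], 1e-4), s)
})

test_that("iron-pattern detection accepts the 54Fe signature and rejects decoys", {
  k <- mass_constants()
  f <- toy_features(c(804.3562, 500.25, 700.30), c(4.5, 3, 5), c(1e8, 1e7, 1e7),
                    ids = c("holo", "lone", "cllike"))
  env <- rbind(
    data.frame(feature_id = "holo",
               iso_mz = c(804.3562 - k$fe_spacing, 804.3562),
               rel_intensity = c(0.064, 1)),
    data.frame(feature_id = "cllike",
               iso_mz = c(700.30 - k$fe_spacing, 700.30),
               rel_intensity = c(0.5, 1)))
  hits <- find_iron_pattern_hits(f, env)
  expect_identical(hits$feature_id, "holo")
  expect_equal(hits$abundance_ratio, 0.064)
  expect_lt(abs(hits$spacing_error_mda), 3)
  ## without envelopes: co-eluting A-2 feature in the table
  f2 <- toy_features(c(804.3562, 804.3562 - k$fe_spacing), c(4.5, 4.5),
                     c(1e8, 0.064e8), ids = c("A", "A2"))
  hits2 <- find_iron_pattern_hits(f2)
  expect_true("A" %in% hits2$feature_id)
})

test_that("apo/holo pairing keys on the 52.91146 Da offset within RT window", {
  f <- toy_features(c(751.4448, 804.3562, 900.4, 953.3615),
                    c(4.1, 4.5, 2.0, 7.0), rep(1e7, 4),
                    ids = c("apo", "holo", "x", "x_holo_far_rt"))
  p <- pair_apo_holo(f)
  expect_identical(p$apo_feature_id, "apo")
  expect_identical(p$holo_feature_id, "holo")
  expect_equal(p$rt_shift, 0.4, tolerance = 1e-9)
  expect_equal(p$apo_fraction, 0.5)
  ## offset wrong by 0.05 Da -> no pair
  f$mz[2] <- 751.4448 + 52.91146 + 0.05
  expect_identical(nrow(pair_apo_holo(f)), 0L)
  ## RT shift beyond the window -> no pair (x vs x_holo_far_rt is 5 min)
  f2 <- toy_features(c(900.4, 953.3115), c(2.0, 7.0), c(1e7, 1e7))
  expect_identical(nrow(pair_apo_holo(f2, rt_window = 2)), 0L)
})

test_that("screen recovers all planted siderophores and no decoys", {
  scn <- generate_scenario(scenario_config(seed = 1))
  scr <- screen_siderophores(scn$sample, scn$control, scn$envelopes)
  expect_identical(nrow(scr$candidates), 5L)
  roles <- scn$truth$role[match(scr$candidates$holo_feature_id,
                                scn$truth$feature_id)]
  expect_true(all(roles == "holo"))
  expect_setequal(scr$candidates$apo_feature_id,
                  scn$truth$feature_id[scn$truth$role == "apo"])
  ## true formulas are among the decomposition candidates
  truth_formula <- scn$truth$formula[match(scr$candidates$holo_feature_id,
                                           scn$truth$feature_id)]
  for (i in seq_len(5))
    expect_true(truth_formula[i] %in%
                  scr$formulas[[scr$candidates$holo_feature_id[i]]]$formula)
})

test_that("screening is invariant to feature order", {
  scn <- generate_scenario(scenario_config(seed = 3))
  scr1 <- screen_siderophores(scn$sample, scn$control, scn$envelopes)
  perm <- sample(nrow(scn$sample))
  scr2 <- screen_siderophores(scn$sample[perm, ], scn$control, scn$envelopes)
  expect_identical(scr1$candidates, scr2$candidates)
})

test_that("recall is 1 and decoy false positives 0 across 20 seeds", {
  for (seed in 1:20) {
    scn <- generate_scenario(scenario_config(seed = seed, envelope_noise = 0.10))
    scr <- screen_siderophores(scn$sample, scn$control, scn$envelopes)
    roles <- scn$truth$role[match(scr$candidates$holo_feature_id,
                                  scn$truth$feature_id)]
    expect_identical(sum(roles == "holo"), 5L)
    expect_identical(nrow(scr$candidates), 5L)
  }
})

test_that("family links record the CH2 and O mass relations", {
  scn <- generate_scenario(scenario_config(seed = 2))
  scr <- screen_siderophores(scn$sample, scn$control, scn$envelopes)
  links <- scr$family_links
  expect_identical(sum(links$relation == "CH2"), 3L)
  expect_identical(sum(links$relation == "O"), 1L)
  expect_true(all(abs(links$delta_mass[links$relation == "CH2"] - 14.0157)
                  <= 0.003))
  expect_true(all(abs(links$delta_mass[links$relation == "O"] - 15.9949)
                  <= 0.003))
})

test_that("screen config semantics: removing evidence removes candidates", {
  scn <- generate_scenario(scenario_config(seed = 1))
  ## no iron envelopes -> no candidates (A-2 partners absent from table)
  env_no_fe <- scn$envelopes[!(scn$envelopes$rel_intensity < 0.9 &
                                 scn$envelopes$iso_mz <
                                   scn$sample$mz[match(scn$envelopes$feature_id,
                                                       scn$sample$feature_id)]), ]
  scr <- screen_siderophores(scn$sample, scn$control, env_no_fe)
  expect_identical(nrow(scr$candidates), 0L)
  ## apo features deleted: nothing in both-required mode, 5 in holo-only mode
  no_apo <- scn$sample[!grepl("^apo", scn$sample$feature_id), ]
  scr2 <- screen_siderophores(no_apo, scn$control, scn$envelopes)
  expect_identical(nrow(scr2$candidates), 0L)
  scr3 <- screen_siderophores(no_apo, scn$control, scn$envelopes,
                              screen_config(require_apo = FALSE))
  expect_identical(nrow(scr3$candidates), 5L)
  expect_true(all(is.na(scr3$candidates$apo_feature_id)))
  ## empty input -> empty output
  scr4 <- screen_siderophores(scn$sample[0, ], scn$control, scn$envelopes)
  expect_identical(nrow(scr4$candidates), 0L)
})
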