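make_spec <- function(mz, int, precursor, id)
  fragment_spectrum(id, precursor, cbind(mz, int), feature_id = id)

test_that("modified cosine: self-similarity, disjoint spectra, symmetry", {
  a <- make_spec(c(100.1, 150.2, 220.3, 301.4), c(10, 200, 50, 400), 450, "a")
  self <- modified_cosine(a, a)
  expect_identical(self$score, 1)
  expect_identical(self$n_matched, 4L)
  b <- make_spec(c(110.0, 160.0, 230.0), c(5, 10, 20), 450, "b")
  expect_identical(modified_cosine(a, b)$score, 0)
  c1 <- make_spec(c(100.1, 150.2, 400.0), c(10, 100, 30), 460, "c")
  ab <- modified_cosine(a, c1); ba <- modified_cosine(c1, a)
  expect_equal(ab$score, ba$score)
  expect_identical(ab$n_matched, ba$n_matched)
  empty <- fragment_spectrum("e", 300, matrix(numeric(0), 0, 2))
  expect_identical(modified_cosine(a, empty)$score, 0)
})

test_that("precursor-shifted analog spectra reach cosine 1", {
  delta <- 14.0157  # CH2 analog
  a <- make_spec(c(86.06, 115.075, 131.081, 500.3, 620.37),
                 c(900, 400, 500, 450, 350), 751.4448, "a")
  b <- a
  b$precursor_mz <- a$precursor_mz + delta
  b$peaks[, "mz"] <- a$peaks[, "mz"] + delta
  expect_equal(modified_cosine(a, b)$score, 1, tolerance = 1e-12)
  expect_identical(modified_cosine(a, b)$n_matched, 5L)
})

test_that("greedy assignment matches the exhaustive oracle and never exceeds it", {
  set.seed(2024)
  n_eq <- 0L
  for (i in 1:1000) {
    p <- random_spectrum_pair()
    g <- modified_cosine(p$a, p$b)
    o <- oracle_modified_cosine(p$a, p$b)
    expect_lte(g$score, o$score + 1e-12)
    if (abs(g$score - o$score) <= 1e-9) n_eq <- n_eq + 1L
  }
  expect_gte(n_eq, 950L)
})

test_that("network respects score, matched-ion and neighbour-cap thresholds", {
  ## two identical 6-peak spectra -> one edge with score 1, n_matched 6
  tmpl <- cbind(c(100.1, 180.2, 260.3, 340.4, 420.5, 500.6),
                c(100, 200, 300, 400, 500, 600))
  two <- lapply(c("n1", "n2"), function(id)
    fragment_spectrum(id, 600, tmpl, feature_id = id))
  g <- build_network(two)
  expect_identical(nrow(g$edges), 1L)
  expect_equal(g$edges$score, 1)
  expect_identical(g$edges$n_matched, 6L)
  ## 12 mutually identical spectra -> all degrees <= 10
  clique <- lapply(sprintf("c%02d", 1:12), function(id)
    fragment_spectrum(id, 600, tmpl, feature_id = id))
  g12 <- build_network(clique)
  deg <- table(c(g12$edges$from, g12$edges$to))
  expect_true(all(deg <= 10))
  expect_true(all(table(c(g12$edges$from, g12$edges$to)) >= 1))
  ## only 4 shared ions -> excluded at min_matched = 5 despite score 1
  four <- lapply(c("m1", "m2"), function(id)
    fragment_spectrum(id, 500, tmpl[1:4, ], feature_id = id))
  expect_identical(nrow(build_network(four)$edges), 0L)
  expect_identical(nrow(build_network(four, min_matched = 4)$edges), 1L)
  ## fewer than 2 spectra -> empty edge set
  expect_identical(nrow(build_network(two[1])$edges), 0L)
})

test_that("an edge below the cosine threshold is excluded", {
  ## 13 equal-intensity peaks, 9 shared: score = 9/13 ~ 0.692 with 9 matches
  shared <- 100 + 0:8 * 45
  a <- make_spec(c(shared, 600, 650, 700, 750), rep(100, 13), 800, "a")
  b <- make_spec(c(shared, 605, 655, 705, 755), rep(100, 13), 800, "b")
  s <- modified_cosine(a, b)
  expect_equal(s$score, 9 / 13, tolerance = 1e-9)
  expect_identical(nrow(build_network(list(a, b), score_min = 0.7)$edges), 0L)
  expect_identical(nrow(build_network(list(a, b), score_min = 0.69)$edges), 1L)
})

test_that("CH2-related synthetic family members join one network component", {
  scn <- generate_scenario(scenario_config(seed = 5))
  spectra <- lapply(scn$spectra, function(s)
    filter_peaks(remove_contaminant(s)))
  g <- build_network(spectra)
  ig <- as_igraph(g)
  comp <- igraph::components(ig)$membership
  apo_ids <- scn$truth$feature_id[scn$truth$role == "apo"]
  apo_ids <- intersect(apo_ids, names(comp))
  expect_gte(length(apo_ids), 5L)
  expect_identical(length(unique(comp[apo_ids])), 1L)
  ## no decoy spectrum joins the siderophore component
  decoy_ids <- intersect(scn$truth$feature_id[scn$truth$role %in%
                                                c("decoy", "blank_shared")],
                         names(comp))
  expect_false(any(comp[decoy_ids] == comp[[apo_ids[1]]]))
})

test_that("GraphML export round-trips nodes, edges and attributes", {
  scn <- generate_scenario(scenario_config(seed = 6))
  spectra <- lapply(scn$spectra, function(s) filter_peaks(remove_contaminant(s)))
  g <- build_network(spectra)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(g, path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_identical(as.integer(igraph::vcount(back)), nrow(g$nodes))
  expect_identical(as.integer(igraph::ecount(back)), nrow(g$edges))
  expect_setequal(igraph::V(back)$name, g$nodes$feature_id)
  expect_equal(sort(igraph::E(back)$score), sort(g$edges$score),
               tolerance = 1e-9)
  expect_equal(sort(igraph::V(back)$mz), sort(g$nodes$mz), tolerance = 1e-9)
  ## empty graph still writes valid GraphML
  g0 <- build_network(list())
  path0 <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(g0, path0)
  expect_identical(as.integer(igraph::vcount(igraph::read_graph(
    path0, format = "graphml"))), 0L)
})
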