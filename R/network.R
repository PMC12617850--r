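#' Modified cosine similarity between two MS/MS spectra
#'
#' Fragment ions of the two precursors are matched either directly (equal
#' m/z within tolerance) or shifted: the difference between two fragment
#' m/z values equals the difference between the precursor m/z values
#' within tolerance. Candidate fragment pairs are reduced to a one-to-one
#' assignment greedily by descending intensity product, and the score is
#' the cosine of the (optionally square-root transformed) intensity
#' vectors over the assigned pairs:
#' score = sum(u_i v_j) / (||u|| ||v||). A pair satisfying both the direct
#' and the shifted condition is counted once.
#'
#' @param a,b [fragment_spectrum()] objects (pre-filter with
#'   [filter_peaks()] for networking).
#' @param tol_ppm,tol_da matching tolerance: 5 ppm or 0.003 Da, whichever
#'   is larger at the fragment m/z.
#' @param transform intensity transform before the cosine, `"sqrt"`
#'   (default, the convention of feature-based molecular networking) or
#'   `"raw"`.
#' @return list of class `similarity_result`: `score` in [0, 1],
#'   `n_matched` fragment pairs, and `pairs` (matrix of matched peak
#'   indices into `a` and `b`). Empty spectra give score 0.
#' @examples
#' s <- fragment_spectrum("s", 300, cbind(c(100, 150, 220), c(1, 2, 3)))
#' modified_cosine(s, s)$score  # 1
#' @export
modified_cosine <- function(a, b, tol_ppm = 5, tol_da = 0.003,
                            transform = c("sqrt", "raw")) {
  transform <- match.arg(transform)
  res0 <- structure(list(score = 0, n_matched = 0L,
                         pairs = matrix(integer(0), 0, 2,
                                        dimnames = list(NULL, c("a", "b")))),
                    class = "similarity_result")
  if (!n_peaks(a) || !n_peaks(b)) return(res0)
  ua <- a$peaks[, "intensity"]; ub <- b$peaks[, "intensity"]
  if (transform == "sqrt") { ua <- sqrt(ua); ub <- sqrt(ub) }
  mza <- a$peaks[, "mz"]; mzb <- b$peaks[, "mz"]
  shift <- a$precursor_mz - b$precursor_mz

  d <- outer(mza, mzb, "-")
  tol <- match_tol(outer(mza, mzb, pmax), tol_ppm, tol_da)
  ok <- abs(d) <= tol | abs(d - shift) <= tol
  idx <- which(ok, arr.ind = TRUE)
  if (!nrow(idx)) return(res0)

  prod <- ua[idx[, 1]] * ub[idx[, 2]]
  ## deterministic greedy: best intensity product first, ties by m/z
  ord <- order(-prod, mza[idx[, 1]], mzb[idx[, 2]])
  idx <- idx[ord, , drop = FALSE]; prod <- prod[ord]
  used_a <- logical(length(mza)); used_b <- logical(length(mzb))
  keep <- logical(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  idx <- idx[keep, , drop = FALSE]
  score <- sum(ua[idx[, 1]] * ub[idx[, 2]]) /
    (sqrt(sum(ua^2)) * sqrt(sum(ub^2)))
  ## snap rounding residue so identical spectra score exactly 1
  if (score > 1 || 1 - score < 1e-12) score <- 1
  dimnames(idx) <- list(NULL, c("a", "b"))
  structure(list(score = score, n_matched = nrow(idx), pairs = idx),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat("<similarity_result> score ", round(x$score, 4), ", ",
      x$n_matched, " matched fragment pair(s)\n", sep = "")
  invisible(x)
}

#' Build a feature-based MS/MS molecular network
#'
#' Computes all-pairs modified-cosine similarities, keeps edges with
#' score >= `score_min` and at least `min_matched` matched fragment ions,
#' and then enforces the neighbour cap: an edge survives only if it ranks
#' within the top `max_neighbors` edges by score for BOTH endpoints
#' (ties broken by score, then matched-ion count, then lexicographic
#' spectrum ids, so the graph is deterministic). Defaults follow the
#' standard feature-based networking parameters: cosine >= 0.7, >= 5
#' matched ions, <= 10 neighbours per node. When several spectra share a
#' feature id, the one with the most intense base peak is kept.
#'
#' @param spectra list of [fragment_spectrum()] objects (already filtered
#'   with [filter_peaks()] / [remove_contaminant()]).
#' @param score_min minimum cosine score, default 0.7.
#' @param min_matched minimum matched fragment ions, default 5.
#' @param max_neighbors neighbour cap per node, default 10.
#' @param tol_ppm,tol_da fragment-matching tolerance.
#' @param transform intensity transform, see [modified_cosine()].
#' @return object of class `molecular_network`: list with `nodes`
#'   (data.frame: `feature_id`, `mz`, `rt`, `n_peaks`) and `edges`
#'   (data.frame: `from`, `to`, `score`, `n_matched`). Undirected, simple,
#'   no self-loops.
#' @export
build_network <- function(spectra, score_min = 0.7, min_matched = 5,
                          max_neighbors = 10, tol_ppm = 5, tol_da = 0.003,
                          transform = "sqrt") {
  stopifnot(score_min >= 0, score_min <= 1, min_matched >= 1,
            max_neighbors >= 1)
  ## one spectrum per feature: keep the most intense
  if (length(spectra) > 1L) {
    fid <- vapply(spectra, function(s) s$feature_id, character(1))
    bp <- vapply(spectra, base_peak_intensity, numeric(1))
    keep <- !duplicated(fid[order(-bp)])[order(order(-bp))]
    keep[is.na(fid)] <- TRUE
    spectra <- spectra[keep]
  }
  ids <- vapply(spectra, function(s)
    if (!is.na(s$feature_id)) s$feature_id else s$spectrum_id, character(1))
  nodes <- data.frame(
    feature_id = ids,
    mz = vapply(spectra, function(s) s$precursor_mz, numeric(1)),
    rt = vapply(spectra, function(s) s$precursor_rt, numeric(1)),
    n_peaks = vapply(spectra, n_peaks, integer(1)),
    stringsAsFactors = FALSE)
  n <- length(spectra)
  edges <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      sim <- modified_cosine(spectra[[i]], spectra[[j]], tol_ppm, tol_da,
                             transform)
      if (sim$score >= score_min && sim$n_matched >= min_matched)
        edges[[length(edges) + 1L]] <- data.frame(
          from = ids[i], to = ids[j], score = sim$score,
          n_matched = sim$n_matched, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), score = numeric(0),
               n_matched = integer(0), stringsAsFactors = FALSE)
  edges <- cap_neighbors(edges, max_neighbors)
  structure(list(nodes = nodes, edges = edges,
                 params = list(score_min = score_min,
                               min_matched = min_matched,
                               max_neighbors = max_neighbors)),
            class = "molecular_network")
}

## keep an edge only if it ranks in the top-k by score for both endpoints
cap_neighbors <- function(edges, k) {
  if (nrow(edges) <= 1L) return(edges)
  edges <- edges[order(-edges$score, -edges$n_matched,
                       pmin(edges$from, edges$to),
                       pmax(edges$from, edges$to)), , drop = FALSE]
  rank_in <- function(node) seq_len(sum(edges$from == node | edges$to == node))
  nodes <- unique(c(edges$from, edges$to))
  rk <- matrix(NA_integer_, nrow(edges), 2)
  cnt <- stats::setNames(integer(length(nodes)), nodes)
  for (e in seq_len(nrow(edges))) {
    cnt[edges$from[e]] <- cnt[edges$from[e]] + 1L
    cnt[edges$to[e]] <- cnt[edges$to[e]] + 1L
    rk[e, ] <- c(cnt[edges$from[e]], cnt[edges$to[e]])
  }
  edges <- edges[rk[, 1] <= k & rk[, 2] <= k, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' @export
print.molecular_network <- function(x, ...) {
  cat("Molecular network:", nrow(x$nodes), "node(s),", nrow(x$edges),
      "edge(s)\n")
  cat("  thresholds: cosine >=", x$params$score_min, "| matched ions >=",
      x$params$min_matched, "| neighbour cap", x$params$max_neighbors, "\n")
  invisible(x)
}

#' Convert a molecular network to an igraph object
#'
#' @param g a `molecular_network`.
#' @return An undirected [igraph::graph] with node attributes (`mz`, `rt`,
#'   and any extra node columns) and edge attributes (`score`,
#'   `n_matched`).
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "molecular_network"))
  igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                vertices = g$nodes)
}

#' Plot a molecular network
#'
#' @param x a `molecular_network`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.molecular_network <- function(x, ...) {
  ig <- as_igraph(x)
  igraph::plot.igraph(ig, vertex.size = 6, vertex.label.cex = 0.6, ...)
  invisible(x)
}

#' Export a molecular network as GraphML for Cytoscape
#'
#' Node attributes carried: precursor m/z, retention time, peak count and
#' any extra columns added to `g$nodes` (e.g. peak area, annotation class,
#' siderophore-candidate flag); edge attributes: cosine score and matched
#' fragment-ion count. The file round-trips through any GraphML reader.
#'
#' @param g a `molecular_network`.
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(g, path) {
  ig <- as_igraph(g)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Write network tables as CSV
#'
#' @param g a `molecular_network`.
#' @param nodes_path,edges_path output CSV paths (either may be `NULL`).
#' @return invisibly, a list of the written paths.
#' @export
export_network_tables <- function(g, nodes_path = NULL, edges_path = NULL) {
  if (!is.null(nodes_path))
    utils::write.csv(g$nodes, nodes_path, row.names = FALSE, quote = FALSE)
  if (!is.null(edges_path))
    utils::write.csv(g$edges, edges_path, row.names = FALSE, quote = FALSE)
  invisible(list(nodes = nodes_path, edges = edges_path))
}
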