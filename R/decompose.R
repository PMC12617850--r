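#' Default element-count bounds for formula decomposition
#'
#' Bounds wide enough to cover small-molecule metabolites up to ~1 kDa
#' without exploding the search space.
#'
#' @return Named list of `c(min, max)` integer ranges per element.
#' @export
default_decomposition_bounds <- function() {
  list(C = c(0L, 60L), H = c(0L, 120L), N = c(0L, 15L),
       O = c(0L, 25L), S = c(0L, 5L))
}

#' Decompose a neutral mass into candidate elemental formulas
#'
#' Exhaustively enumerates CHNOS formulas within per-element count bounds
#' whose monoisotopic mass lies within a ppm tolerance of the target, then
#' filters by ring-and-double-bond equivalents and (optionally) H/C ratio.
#' Candidates are returned sorted by absolute ppm error, ties broken by the
#' Hill-notation formula string, so the order is fully deterministic.
#'
#' Internally the heavy-element grid (C, N, O, S) is enumerated and the
#' hydrogen count is solved from the residual mass, which keeps the search
#' linear in the grid size; a naive nested-loop enumeration gives
#' identical results.
#'
#' @param neutral_mass target neutral monoisotopic mass (Da).
#' @param tol_ppm mass tolerance in ppm (> 0), default 5.
#' @param bounds named list of `c(min, max)` count ranges, as
#'   [default_decomposition_bounds()].
#' @param rdbe_range numeric length-2, allowed RDBE interval, default
#'   `c(0, 40)`.
#' @param hc_range optional H/C ratio filter, e.g. `c(0.2, 3.1)`; `NULL`
#'   (default) disables it.
#' @return A data.frame with columns `formula` (Hill string), one column
#'   per element in `bounds`, `mass` (Da), `mass_error_ppm` (signed),
#'   `rdbe`; zero rows when nothing matches.
#' @examples
#' decompose_mass(18.0106)[, c("formula", "mass_error_ppm")]  # H2O
#' head(decompose_mass(114.0681))
#' @export
decompose_mass <- function(neutral_mass, tol_ppm = 5,
                           bounds = default_decomposition_bounds(),
                           rdbe_range = c(0, 40), hc_range = NULL) {
  stopifnot(is.numeric(neutral_mass), neutral_mass > 0, tol_ppm > 0)
  ms <- mass_constants()$masses
  unknown <- setdiff(names(bounds), names(ms))
  if (length(unknown))
    stop("no mass for element(s): ", paste(unknown, collapse = ", "))
  tol_da <- tol_ppm * 1e-6 * neutral_mass
  hmass <- ms[["H"]]

  heavy <- setdiff(names(bounds), "H")
  ranges <- lapply(heavy, function(e) {
    b <- bounds[[e]]
    hi <- min(b[2], floor((neutral_mass + tol_da) / ms[[e]]))
    if (hi < b[1]) return(integer(0))
    seq.int(b[1], hi)
  })
  names(ranges) <- heavy
  if (any(vapply(ranges, length, 1L) == 0L)) return(empty_decomposition(bounds))

  grid <- do.call(expand.grid, c(ranges, KEEP.OUT.ATTRS = FALSE))
  partial <- as.numeric(as.matrix(grid) %*% ms[heavy])
  keep <- partial <= neutral_mass + tol_da
  grid <- grid[keep, , drop = FALSE]
  partial <- partial[keep]
  if (nrow(grid) == 0L) return(empty_decomposition(bounds))

  hb <- if ("H" %in% names(bounds)) bounds[["H"]] else c(0L, 0L)
  resid <- neutral_mass - partial
  ## hydrogen counts whose mass lands inside [resid - tol, resid + tol]
  hlo <- pmax(hb[1], ceiling((resid - tol_da) / hmass))
  hhi <- pmin(hb[2], floor((resid + tol_da) / hmass))
  ## residual ~0 admits H = 0 as well
  hlo[resid <= tol_da] <- pmin(hlo[resid <= tol_da], hb[1])
  rows <- which(hhi >= hlo)
  if (length(rows) == 0L) return(empty_decomposition(bounds))

  out <- do.call(rbind, lapply(rows, function(i) {
    hs <- seq.int(hlo[i], hhi[i])
    data.frame(grid[rep(i, length(hs)), , drop = FALSE], H = hs,
               row.names = NULL)
  }))
  elems <- c(heavy, "H")
  mass <- as.numeric(as.matrix(out[elems]) %*% ms[elems])
  err <- ppm_error(neutral_mass, mass)
  rd <- (2 * getcol(out, "C") + 2 + getcol(out, "N") - out$H) / 2
  keep <- abs(err) <= tol_ppm & rd >= rdbe_range[1] & rd <= rdbe_range[2]
  if (!is.null(hc_range)) {
    hc <- ifelse(getcol(out, "C") > 0, out$H / getcol(out, "C"), NA_real_)
    keep <- keep & (!is.na(hc) & hc >= hc_range[1] & hc <= hc_range[2])
  }
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L) return(empty_decomposition(bounds))
  mass <- mass[keep]; err <- err[keep]; rd <- rd[keep]

  fstr <- vapply(seq_len(nrow(out)), function(i) {
    v <- as.integer(out[i, elems]); names(v) <- elems
    format_formula(as_chem_formula(v))
  }, character(1))
  res <- data.frame(formula = fstr,
                    out[c(intersect(c("C", "H"), elems), sort(setdiff(elems, c("C", "H"))))],
                    mass = mass, mass_error_ppm = err, rdbe = rd,
                    stringsAsFactors = FALSE, row.names = NULL)
  res[order(abs(res$mass_error_ppm), res$formula), , drop = FALSE] |>
    `rownames<-`(NULL)
}

getcol <- function(df, nm) if (nm %in% names(df)) df[[nm]] else rep(0, nrow(df))

empty_decomposition <- function(bounds) {
  elems <- names(bounds)
  elems <- c(intersect(c("C", "H"), elems), sort(setdiff(elems, c("C", "H"))))
  cols <- c(list(formula = character(0)),
            stats::setNames(rep(list(integer(0)), length(elems)), elems),
            list(mass = numeric(0), mass_error_ppm = numeric(0),
                 rdbe = numeric(0)))
  as.data.frame(cols, stringsAsFactors = FALSE)
}
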