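## Independent oracles used to cross-check the package implementations.

## Naive nested-loop formula enumeration: every (C, N, O, S) combination in
## bounds is visited explicitly and every hydrogen count is mass-checked.
oracle_decompose <- function(neutral_mass, tol_ppm = 5,
                             bounds = default_decomposition_bounds(),
                             rdbe_range = c(0, 40)) {
  ms <- mass_constants()$masses
  tol <- tol_ppm * 1e-6 * neutral_mass
  hs <- seq.int(bounds$H[1], bounds$H[2])
  sb <- if ("S" %in% names(bounds)) seq.int(bounds$S[1], bounds$S[2]) else 0L
  rows <- list()
  for (C in seq.int(bounds$C[1], bounds$C[2])) {
    if (C * ms[["C"]] > neutral_mass + tol) break
    for (N in seq.int(bounds$N[1], bounds$N[2])) {
      if (C * ms[["C"]] + N * ms[["N"]] > neutral_mass + tol) break
      for (O in seq.int(bounds$O[1], bounds$O[2])) {
        base <- C * ms[["C"]] + N * ms[["N"]] + O * ms[["O"]]
        if (base > neutral_mass + tol) break
        for (S in sb) {
          mass <- base + S * ms[["S"]] + hs * ms[["H"]]
          ok <- which(abs(mass - neutral_mass) <= tol)
          for (i in ok) {
            rd <- (2 * C + 2 + N - hs[i]) / 2
            if (rd < rdbe_range[1] || rd > rdbe_range[2]) next
            rows[[length(rows) + 1L]] <- data.frame(
              C = C, H = hs[i], N = N, O = O, S = S, mass = mass[i],
              mass_error_ppm = 1e6 * (neutral_mass - mass[i]) / mass[i],
              rdbe = rd)
          }
        }
      }
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out$formula <- apply(out[c("C", "H", "N", "O", "S")], 1, function(v)
    format_formula(structure(as.integer(v), names = c("C", "H", "N", "O", "S"),
                             class = "chem_formula")))
  out[order(abs(out$mass_error_ppm), out$formula), ]
}

## Exhaustive optimal-assignment modified cosine for small spectra:
## enumerates every injective mapping from peaks of `a` to peaks of `b`
## (or unmatched) over the same candidate-pair set as modified_cosine.
oracle_modified_cosine <- function(a, b, tol_ppm = 5, tol_da = 0.003) {
  if (nrow(a$peaks) == 0L || nrow(b$peaks) == 0L)
    return(list(score = 0, n_matched = 0L))
  ua <- sqrt(a$peaks[, "intensity"]); ub <- sqrt(b$peaks[, "intensity"])
  mza <- a$peaks[, "mz"]; mzb <- b$peaks[, "mz"]
  shift <- a$precursor_mz - b$precursor_mz
  allowed <- lapply(seq_along(mza), function(i) {
    tol <- pmax(tol_da, tol_ppm * 1e-6 * pmax(mza[i], mzb))
    which(abs(mza[i] - mzb) <= tol | abs((mza[i] - mzb) - shift) <= tol)
  })
  best <- 0; best_n <- 0L
  recurse <- function(i, used, acc, n) {
    if (i > length(mza)) {
      if (acc > best || (acc == best && n > best_n)) {
        best <<- acc; best_n <<- n
      }
      return(invisible())
    }
    recurse(i + 1L, used, acc, n)            # peak i unmatched
    for (j in allowed[[i]]) if (!used[j]) {
      used[j] <- TRUE
      recurse(i + 1L, used, acc + ua[i] * ub[j], n + 1L)
      used[j] <- FALSE
    }
  }
  recurse(1L, logical(length(mzb)), 0, 0L)
  list(score = best / (sqrt(sum(ua^2)) * sqrt(sum(ub^2))), n_matched = best_n)
}

## random small spectra with a controllable amount of direct and
## precursor-shifted peak overlap, for greedy-vs-optimal comparisons
random_spectrum_pair <- function() {
  pa <- runif(1, 300, 800)
  shift <- runif(1, -30, 30)
  pb <- pa - shift
  n_a <- sample(2:6, 1)
  mza <- sort(runif(n_a, 100, 280))
  n_common <- sample(0:min(3, n_a), 1)
  n_shifted <- sample(0:min(2, n_a), 1)
  mzb <- c(if (n_common) sample(mza, n_common) + rnorm(n_common, 0, 5e-4),
           if (n_shifted) sample(mza, n_shifted) - shift +
             rnorm(n_shifted, 0, 5e-4),
           runif(max(0, 6 - n_common - n_shifted), 100, 280))
  mzb <- mzb[seq_len(min(6, length(mzb)))]
  a <- fragment_spectrum("a", pa, cbind(mza, runif(n_a, 10, 1000)))
  b <- fragment_spectrum("b", pb, cbind(mzb, runif(length(mzb), 10, 1000)))
  list(a = a, b = b)
}
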