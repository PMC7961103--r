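# Independent oracles used to cross-check the package's algorithms.

# Brute-force natural-abundance envelope: convolve the per-atom isotope
# distribution one atom at a time (no binary exponentiation, no
# truncation tricks beyond the requested depth). Patterns restated here
# independently of the package's constants.
ORACLE_ABUNDANCE <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205)
)

brute_envelope <- function(counts, n_peaks) {
  acc <- 1
  for (sym in names(counts)) {
    pat <- ORACLE_ABUNDANCE[[sym]]
    if (is.null(pat)) next
    for (k in seq_len(counts[[sym]])) {
      new <- rep(0, length(acc) + length(pat) - 1)
      for (i in seq_along(acc)) {
        new[i:(i + length(pat) - 1)] <- new[i:(i + length(pat) - 1)] + acc[i] * pat
      }
      acc <- new
    }
  }
  acc <- c(acc, rep(0, n_peaks))[seq_len(n_peaks)]
  acc / acc[1]
}

# O(n^2) greedy clustering oracle: seed at the most intense unassigned
# peak, sweep all unassigned peaks linearly for membership.
brute_cluster <- function(mz, intensity, tol_ppm) {
  n <- length(mz)
  assignment <- rep(0L, n)
  centers <- numeric(0)
  k <- 0L
  while (any(assignment == 0L)) {
    free <- which(assignment == 0L)
    seed_i <- free[which.max(intensity[free])]
    k <- k + 1L
    tol <- mz[seed_i] * tol_ppm * 1e-6
    members <- free[abs(mz[free] - mz[seed_i]) <= tol]
    assignment[members] <- k
    centers[k] <- sum(mz[members] * intensity[members]) / sum(intensity[members])
  }
  list(assignment = assignment, center = centers)
}

# partition signature (which peaks share a cluster), order-independent
cluster_signature <- function(assignment) {
  unname(split(seq_along(assignment), assignment)[
    order(vapply(split(seq_along(assignment), assignment), min, numeric(1)))])
}
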