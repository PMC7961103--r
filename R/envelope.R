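#' Natural-abundance isotopologue envelope
#'
#' Aggregated isotopologue intensities for M+0 ... M+(n_peaks-1) by
#' element-wise polynomial convolution of per-atom natural-abundance
#' patterns, normalised so that M+0 = 1. Sites already substituted by a
#' label (13C, D) are isotopically pure and contribute no further
#' heavy-isotope probability; this matters when emulating the envelope
#' of a universally labelled tracer. Fine structure within a nominal
#' mass is aggregated (the sum of probabilities at each nominal shift);
#' peak positions are reported at the dominant 13C spacing.
#'
#' @param formula An [elemental_formula()], formula string, or
#'   [lipid_species()].
#' @param n_peaks Number of isotopologue peaks to report (>= 1).
#' @return A tibble with columns `peak` (0-based isotopologue index),
#'   `mass_offset` (Da relative to the monoisotopic peak) and
#'   `relative_abundance` (fraction of M+0).
#' @examples
#' isotopologue_envelope(pc_sum_formula(32, 0), n_peaks = 3)
#' @export
isotopologue_envelope <- function(formula, n_peaks = 3) {
  if (n_peaks < 1) stop("n_peaks must be >= 1", call. = FALSE)
  formula <- as_formula(formula)
  dist <- envelope_distribution(formula, n_peaks)
  if (dist[1] <= 0) {
    # degenerate only for the empty formula, where every shift is certain
    dist <- c(1, rep(0, n_peaks - 1))
  }
  tibble::tibble(
    peak = seq_len(n_peaks) - 1L,
    mass_offset = (seq_len(n_peaks) - 1) * C13_C12_DELTA,
    relative_abundance = dist / dist[1]
  )
}

# probability mass over nominal shifts 0..n_peaks-1 (unnormalised tail
# truncated); exact within the truncation, used directly by tests against
# a brute-force expansion
envelope_distribution <- function(formula, n_peaks) {
  acc <- c(1, rep(0, n_peaks - 1))
  for (sym in names(formula)) {
    pat <- NATURAL_ABUNDANCE[[sym]]
    if (is.null(pat)) next  # monoisotopic or isotopically pure site
    n <- formula_count(formula, sym)
    single <- rep(0, n_peaks)
    keep <- pat$shift < n_peaks
    single[pat$shift[keep] + 1] <- pat$prob[keep]
    acc <- conv_trunc(acc, pow_trunc(single, n, n_peaks), n_peaks)
  }
  acc
}

# truncated linear convolution of probability vectors
conv_trunc <- function(a, b, n) {
  out <- rep(0, n)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    jmax <- n - i + 1
    out[i:(i + jmax - 1)] <- out[i:(i + jmax - 1)] + a[i] * b[seq_len(jmax)]
  }
  out
}

# x convolved with itself n times, by binary exponentiation
pow_trunc <- function(x, n, len) {
  out <- c(1, rep(0, len - 1))
  base <- x
  while (n > 0) {
    if (n %% 2 == 1) out <- conv_trunc(out, base, len)
    base <- conv_trunc(base, base, len)
    n <- n %/% 2
  }
  out
}
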