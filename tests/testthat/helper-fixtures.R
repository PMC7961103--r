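# Shared fixtures, built in code at test time.

# a tiny hand-written dataset: explicit spectra on a small grid
tiny_dataset <- function(spectra = NULL, grid = c(2, 2)) {
  if (is.null(spectra)) {
    spectra <- tibble::tibble(
      x = c(0L, 1L, 0L, 1L),
      y = c(0L, 0L, 1L, 1L),
      mz = list(c(400, 500, 756.5514), c(400, 756.5514),
                c(500, 756.5514), c(400, 500)),
      intensity = list(c(10, 5, 100), c(8, 90), c(6, 80), c(12, 7))
    )
  }
  msi_dataset(spectra, grid_shape = grid)
}

# memoised study-condition phantom shared across tests: 64 x 64 grid,
# 5 ppm drift, defaults otherwise (1% D9, 0.1% remodelling product,
# 2.5x deposition enhancement)
study_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_phantom(phantom_config(drift_ppm = 5, seed = 1))
    }
    cache
  }
})

lock_mz_pc320 <- function() adduct_mz(pc_sum_formula(32, 0), "Na")

theoretical_mz <- function(name, adduct = "Na") {
  adduct_mz(monoisotopic_mass(parse_species(name)$formula), adduct)
}
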