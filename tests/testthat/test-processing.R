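make_shifted_dataset <- function(shift_ppm) {
  lock <- lock_mz_pc320()
  base_mz <- c(700.4, lock, 780.7)
  spectra <- tibble::tibble(
    x = 0L, y = 0L,
    mz = list(base_mz * (1 + shift_ppm * 1e-6)),
    intensity = list(c(10, 100, 20))
  )
  msi_dataset(spectra, grid_shape = c(1, 1))
}

test_that("lock-mass recalibration inverts a uniform ppm shift", {
  lock <- lock_mz_pc320()
  ds <- make_shifted_dataset(5)
  rec <- recalibrate_lock_mass(ds, lock, search_tol_ppm = 20)
  expect_true(all(rec$metadata$lock_found))
  got <- rec$spectra$mz[[1]]
  expect_equal(got[2], lock, tolerance = 1e-5 / lock)
  # all peaks de-shifted by the same factor
  expect_equal(got, c(700.4, lock, 780.7), tolerance = 1e-9)
})

test_that("recalibration is a fixed point on calibrated spectra", {
  lock <- lock_mz_pc320()
  ds <- make_shifted_dataset(0)
  rec <- recalibrate_lock_mass(ds, lock)
  expect_equal(rec$spectra$mz[[1]], ds$spectra$mz[[1]], tolerance = 1e-9)
})

test_that("spectra without a lock peak are returned unchanged and flagged", {
  ds <- msi_dataset(tibble::tibble(
    x = 0L, y = 0L, mz = list(c(400.0, 500.0)), intensity = list(c(1, 2))),
    grid_shape = c(1, 1))
  rec <- recalibrate_lock_mass(ds, lock_mz_pc320(), search_tol_ppm = 20)
  expect_false(any(rec$metadata$lock_found))
  expect_identical(rec$spectra$mz, ds$spectra$mz)
})

test_that("alignment keeps low-frequency features and drops sub-threshold ones", {
  # a peak present in 1 of 3 pixels (33% > 0.5% min frequency) is kept;
  # a peak at 1e-5 of the base peak in every pixel is dropped
  spectra <- tibble::tibble(
    x = 0:2, y = 0L,
    mz = list(c(500.0, 600.0, 700.0), c(500.0, 700.0), c(500.0, 700.0)),
    intensity = list(c(1000, 50, 0.01), c(900, 0.01), c(950, 0.01))
  )
  ds <- msi_dataset(spectra, grid_shape = c(3, 1))
  pt <- pick_and_align_peaks(ds, relative_intensity_threshold = 0.0005,
                             min_frequency = 0.005, align_tol_ppm = 3)
  expect_true(any(abs(pt$features$mz - 600) < 0.01))
  expect_false(any(abs(pt$features$mz - 700) < 0.01))
})

test_that("peaks merge within tolerance and split beyond it", {
  two_pixel <- function(delta_ppm) {
    msi_dataset(tibble::tibble(
      x = 0:1, y = 0L,
      mz = list(600.0, 600.0 * (1 + delta_ppm * 1e-6)),
      intensity = list(100, 100)), grid_shape = c(2, 1))
  }
  pt2 <- pick_and_align_peaks(two_pixel(2), 1e-6, 1e-6, align_tol_ppm = 3)
  expect_identical(nrow(pt2$features), 1L)
  pt5 <- pick_and_align_peaks(two_pixel(5), 1e-6, 1e-6, align_tol_ppm = 3)
  expect_identical(nrow(pt5$features), 2L)
})

test_that("alignment equals the O(n^2) clustering oracle on random toys", {
  withr::local_seed(7)
  for (rep in 1:5) {
    n <- sample(20:100, 1)
    centers <- stats::runif(8, 400, 900)
    mz <- centers[sample(8, n, replace = TRUE)] *
      (1 + stats::rnorm(n, 0, 1) * 1e-6)
    intensity <- stats::runif(n, 1, 100)
    got <- pctracer:::cluster_peaks_greedy(mz, intensity, 3)
    want <- brute_cluster(mz, intensity, 3)
    expect_identical(cluster_signature(got$assignment),
                     cluster_signature(want$assignment))
    expect_equal(sort(got$center), sort(want$center), tolerance = 1e-12)
  }
})

test_that("mean spectrum averages features over all pixels with zeros", {
  spectra <- tibble::tibble(
    x = 0:3, y = 0L,
    mz = list(c(500.0, 600.0), c(500.0), c(500.0), c(500.0)),
    intensity = list(c(10, 8), c(10), c(10), c(10))
  )
  ds <- msi_dataset(spectra, grid_shape = c(4, 1))
  pt <- pick_and_align_peaks(ds, 1e-9, 1e-9, 3)
  ms <- mean_spectrum(ds, pt)
  expect_equal(ms$intensity[abs(ms$mz - 500) < 0.01], 10)  # identical pixels
  expect_equal(ms$intensity[abs(ms$mz - 600) < 0.01], 2)   # 8 in 1 of 4
})

test_that("ion image extraction sums the window and normalises by TIC", {
  ds <- msi_dataset(tibble::tibble(
    x = 0L, y = 0L,
    mz = list(c(500.0, 600.0, 600.0005, 700.0)),
    intensity = list(c(32, 3, 5, 4))), grid_shape = c(1, 1))
  img_raw <- extract_ion_image(ds, 600.0002, tol_ppm = 3, "none")
  expect_equal(img_raw$values[1, 1], 8)  # two in-window peaks, 3 + 5
  img_tic <- extract_ion_image(ds, 700.0, tol_ppm = 3, "tic")
  expect_equal(img_tic$values[1, 1], 4 / 44)
  img_none <- extract_ion_image(ds, 450.0, tol_ppm = 3)
  expect_identical(img_none$values[1, 1], 0)  # acquired but absent: 0, not NA
  expect_error(extract_ion_image(ds, 600, tol_ppm = 0), "positive")
})

test_that("single in-window peak at a tenth of TIC gives 0.1 under TIC mode", {
  ds <- msi_dataset(tibble::tibble(
    x = 0L, y = 0L, mz = list(c(500.0, 600.0)),
    intensity = list(c(36, 4))), grid_shape = c(1, 1))
  img <- extract_ion_image(ds, 600.0, 3, "tic")
  expect_equal(img$values[1, 1], 0.1)
})

test_that("image extraction is additive over disjoint windows", {
  ph <- generate_phantom(phantom_config(grid_shape = c(8, 8), seed = 3,
                                        drift_ppm = 0))
  m0 <- lock_mz_pc320()                      # DPPC+Na monoisotopic peak
  m1 <- m0 + 1.0033548                       # its M+1 isotopologue
  a <- extract_ion_image(ph$dataset, m0, 3)
  b <- extract_ion_image(ph$dataset, m1, 3)
  centre <- (m0 + m1) / 2
  wide_tol <- ((m1 - m0) / 2 / centre) * 1e6 + 3
  wide <- extract_ion_image(ph$dataset, centre, wide_tol)
  expect_equal(a$values + b$values, wide$values, tolerance = 1e-12)
})

test_that("TIC-normalised features sum to one when they cover the spectrum", {
  ph <- generate_phantom(phantom_config(grid_shape = c(6, 6), seed = 5,
                                        drift_ppm = 0))
  pt <- pick_and_align_peaks(ph$dataset, 1e-12, 1e-12, 3)
  total <- Reduce(`+`, lapply(pt$features$mz, function(m)
    extract_ion_image(ph$dataset, m, 3, "tic")$values))
  expect_equal(as.vector(total), rep(1, 36), tolerance = 1e-9)
})

test_that("hotspot clipping matches the type-7 quantile and is idempotent", {
  vals <- c(rep(1, 100), 1000)
  img <- ion_image(matrix(vals, nrow = 1))
  clipped <- hotspot_clip(img, 0.99)
  q <- stats::quantile(vals, 0.99, type = 7, names = FALSE)
  expect_equal(max(clipped$values), q)
  expect_equal(clipped$values[1, 101], q)
  expect_equal(clipped$values[1, 1:100], vals[1:100])  # at/below q untouched
  twice <- hotspot_clip(clipped, 0.99)
  expect_equal(twice$values, clipped$values)
  # never increases, preserves values at or below the quantile
  expect_true(all(clipped$values <= img$values))
  const <- hotspot_clip(ion_image(matrix(5, 3, 3)), 0.99)
  expect_equal(const$values, matrix(5, 3, 3))
  expect_error(hotspot_clip(ion_image(matrix(NA_real_, 2, 2)), 0.99), "missing")
  expect_error(hotspot_clip(img, 0), "quantile")
})

test_that("ratio images divide pixelwise and mark undefined pixels missing", {
  num <- ion_image(matrix(c(0.01, 0.02, 0, 0.04), 2))
  den <- ion_image(matrix(c(1, 2, 0, 4), 2))
  r <- ratio_image(num, den)
  expect_equal(r$values[is.finite(r$values)], c(0.01, 0.01, 0.01))
  expect_true(is.na(r$values[1, 2]))  # zero denominator
  # ~1% labelling ratio construction
  unlab <- ion_image(matrix(stats::runif(16, 1, 5), 4))
  lab <- ion_image(unlab$values * 0.01)
  expect_equal(ratio_image(lab, unlab)$values, matrix(0.01, 4, 4))
  # scale invariance of the ratio under a global intensity factor
  r7 <- ratio_image(ion_image(lab$values * 7), ion_image(unlab$values * 7))
  expect_equal(r7$values, ratio_image(lab, unlab)$values, tolerance = 1e-12)
  expect_error(ratio_image(num, ion_image(matrix(1, 3, 3))), "shapes")
  expect_error(
    ratio_image(num, ion_image(matrix(1, 2, 2), normalization = "tic")),
    "normalization")
})

test_that("overlays scale channels independently and respect masks", {
  const <- ion_image(matrix(2, 4, 4))
  ov <- overlay_channels(list(const), "red")
  expect_equal(ov$rgb[, , 1], matrix(1, 4, 4))
  expect_equal(ov$rgb[, , 2], matrix(0, 4, 4))
  left <- matrix(0, 4, 4); left[, 1:2] <- 5
  right <- matrix(0, 4, 4); right[, 3:4] <- 7
  ov2 <- overlay_channels(list(ion_image(left), ion_image(right)),
                          c("red", "green"))
  expect_false(any(ov2$rgb[, , 1] > 0 & ov2$rgb[, , 2] > 0))
  expect_error(overlay_channels(rep(list(const), 4)), "1 to 3")
})

test_that("phantom species overlays align with the ground-truth regions", {
  ph <- study_phantom()
  ds <- recalibrate_lock_mass(ph$dataset, lock_mz_pc320())
  imgs <- list(
    extract_ion_image(ds, theoretical_mz("13C24-PC16:0_20:4")),  # red
    extract_ion_image(ds, theoretical_mz("PC36:4")),             # green
    extract_ion_image(ds, theoretical_mz("U13C-PC32:0"))         # blue
  )
  ov <- overlay_channels(imgs, c("red", "green", "blue"))
  masks <- ph$truth$masks
  agree <- function(channel, mask) {
    mean((ov$rgb[, , channel] > 0) == mask$values)
  }
  expect_gt(agree(1, masks$parenchyma), 0.95)   # remodelling product
  expect_gt(agree(2, masks$bronchiole), 0.95)   # polyunsaturated marker
  expect_gt(agree(3, masks$deposition), 0.95)   # exogenous surfactant
})
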