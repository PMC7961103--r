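#' Construct an MSI dataset
#'
#' The in-memory model of a mass spectrometry imaging acquisition: one
#' centroid spectrum per pixel, held as a tibble with list-columns for
#' the m/z and intensity arrays. Pixel coordinates are 0-based, `x` the
#' column increasing rightward and `y` the row increasing downward
#' (image convention). Row order of `spectra` is the acquisition order
#' and is preserved by all I/O.
#'
#' @param spectra A tibble (or data frame) with columns `x`, `y`
#'   (integer pixel coordinates), `mz` (list of strictly increasing
#'   numeric vectors) and `intensity` (list of non-negative numeric
#'   vectors of matching length).
#' @param grid_shape Integer `c(n_columns, n_rows)`.
#' @param pixel_size_um Physical pixel edge in micrometres.
#' @param metadata Free-form named list (instrument, mode, seed, ...).
#' @return An `msi_dataset` object.
#' @export
msi_dataset <- function(spectra, grid_shape, pixel_size_um = 40,
                        metadata = list()) {
  spectra <- tibble::as_tibble(spectra)
  required <- c("x", "y", "mz", "intensity")
  if (!all(required %in% names(spectra))) {
    stop("spectra must have columns x, y, mz, intensity", call. = FALSE)
  }
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1))
  if (nrow(spectra) > 0) {
    if (any(spectra$x < 0) || any(spectra$x >= grid_shape[1]) ||
        any(spectra$y < 0) || any(spectra$y >= grid_shape[2])) {
      stop("pixel coordinates fall outside the grid", call. = FALSE)
    }
    if (anyDuplicated(spectra[c("x", "y")]) > 0) {
      stop("duplicate pixel coordinates", call. = FALSE)
    }
    lens_mz <- lengths(spectra$mz)
    lens_int <- lengths(spectra$intensity)
    if (!all(lens_mz == lens_int)) {
      stop("m/z and intensity arrays differ in length", call. = FALSE)
    }
    bad_sort <- vapply(spectra$mz, function(v) is.unsorted(v, strictly = TRUE),
                       logical(1))
    if (any(bad_sort)) {
      stop("m/z arrays must be strictly increasing (pixel row ",
           which(bad_sort)[1], ")", call. = FALSE)
    }
    if (any(vapply(spectra$intensity, function(v) any(v < 0), logical(1)))) {
      stop("intensities must be non-negative", call. = FALSE)
    }
  }
  spectra$tic <- vapply(spectra$intensity, sum, numeric(1))
  structure(list(
    spectra = spectra[c("x", "y", "mz", "intensity", "tic")],
    grid_shape = grid_shape,
    pixel_size_um = pixel_size_um,
    metadata = metadata
  ), class = "msi_dataset")
}

#' Number of pixels in a dataset
#' @param dataset An [msi_dataset()].
#' @return Integer count of acquired pixels.
#' @export
n_pixels <- function(dataset) nrow(dataset$spectra)

#' @export
print.msi_dataset <- function(x, ...) {
  cat("<msi_dataset> ", n_pixels(x), " pixels on a ",
      x$grid_shape[1], " x ", x$grid_shape[2], " grid (",
      x$pixel_size_um, " um pixels)\n", sep = "")
  npk <- sum(lengths(x$spectra$mz))
  cat("  ", npk, " centroid peaks total",
      if (npk > 0) paste0(", m/z ", sprintf("%.4f", min(unlist(x$spectra$mz))),
                          " - ", sprintf("%.4f", max(unlist(x$spectra$mz)))),
      "\n", sep = "")
  invisible(x)
}

#' Long-format peak table of a dataset
#'
#' @param x An [msi_dataset()].
#' @param ... Unused.
#' @return A tibble with one row per centroid peak: `pixel`, `x`, `y`,
#'   `mz`, `intensity`, `tic`.
#' @method as_tibble msi_dataset
#' @export
as_tibble.msi_dataset <- function(x, ...) {
  sp <- x$spectra
  tibble::tibble(
    pixel = rep(seq_len(nrow(sp)), lengths(sp$mz)),
    x = rep(sp$x, lengths(sp$mz)),
    y = rep(sp$y, lengths(sp$mz)),
    mz = unlist(sp$mz, use.names = FALSE),
    intensity = unlist(sp$intensity, use.names = FALSE),
    tic = rep(sp$tic, lengths(sp$mz))
  )
}
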