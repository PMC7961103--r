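#' Ion image objects
#'
#' An ion image is a 2-D grid of per-pixel intensities for one m/z
#' window, stored as an `n_rows x n_columns` matrix (`values[y + 1, x + 1]`
#' addresses pixel `(x, y)`). Pixels that were not acquired, or whose
#' normalisation is undefined (zero TIC, zero ratio denominator), are
#' `NA` — explicitly missing, never silently zero.
#'
#' @param values Numeric matrix (rows = y, columns = x).
#' @param target_mz Centre of the extraction window (NA for derived
#'   images).
#' @param tol_ppm Window half-width in ppm.
#' @param normalization One of `"none"`, `"tic"`, `"denominator"`.
#' @param clipped_quantile Quantile at which the image was hotspot
#'   clipped, or `NULL`.
#' @return An `ion_image` object.
#' @export
ion_image <- function(values, target_mz = NA_real_, tol_ppm = NA_real_,
                      normalization = "none", clipped_quantile = NULL) {
  stopifnot(is.matrix(values))
  if (any(values < 0, na.rm = TRUE)) {
    stop("ion image intensities must be non-negative", call. = FALSE)
  }
  structure(list(values = values, target_mz = target_mz, tol_ppm = tol_ppm,
                 normalization = normalization,
                 clipped_quantile = clipped_quantile),
            class = "ion_image")
}

#' @export
print.ion_image <- function(x, ...) {
  cat("<ion_image> ", nrow(x$values), " x ", ncol(x$values), " (rows x cols)",
      if (!is.na(x$target_mz)) paste0(", m/z ", sprintf("%.4f", x$target_mz),
                                      " +/- ", x$tol_ppm, " ppm"),
      ", normalization: ", x$normalization,
      if (!is.null(x$clipped_quantile)) paste0(", clipped at q=", x$clipped_quantile),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn ion_image Tidy the image into a `(x, y, value)` tibble.
#' @param x An `ion_image`.
#' @param ... Unused.
#' @method as_tibble ion_image
#' @export
as_tibble.ion_image <- function(x, ...) {
  v <- x$values
  tibble::tibble(
    x = rep(seq_len(ncol(v)) - 1L, each = nrow(v)),
    y = rep(seq_len(nrow(v)) - 1L, times = ncol(v)),
    value = as.vector(v)
  )
}

#' Extract an ion image from a dataset
#'
#' Per pixel, sums the intensities of all centroid peaks falling inside
#' the symmetric, closed ppm window around `target_mz`. With
#' `normalization = "tic"` the per-pixel sum is divided by that pixel's
#' total ion current; pixels with zero TIC become missing. Pixels with
#' no in-window peak are 0 (they were acquired — the ion is absent),
#' not missing.
#'
#' @param dataset An [msi_dataset()].
#' @param target_mz Window centre m/z.
#' @param tol_ppm Window half-width in ppm (> 0); the default matches
#'   the 3 ppm alignment tolerance.
#' @param normalization `"none"` or `"tic"`.
#' @return An [ion_image()].
#' @export
extract_ion_image <- function(dataset, target_mz, tol_ppm = 3,
                              normalization = c("none", "tic")) {
  stopifnot(inherits(dataset, "msi_dataset"))
  normalization <- match.arg(normalization)
  if (tol_ppm <= 0) stop("tol_ppm must be positive", call. = FALSE)
  tol <- target_mz * tol_ppm * 1e-6
  lo <- target_mz - tol
  hi <- target_mz + tol
  sp <- dataset$spectra
  sums <- purrr::map2_dbl(sp$mz, sp$intensity, function(mz, int) {
    i1 <- findInterval(lo, mz, left.open = TRUE) + 1L
    i2 <- findInterval(hi, mz)
    if (i2 < i1) 0 else sum(int[i1:i2])
  })
  if (normalization == "tic") {
    sums <- ifelse(sp$tic > 0, sums / sp$tic, NA_real_)
  }
  values <- matrix(NA_real_, nrow = dataset$grid_shape[2],
                   ncol = dataset$grid_shape[1])
  values[cbind(sp$y + 1L, sp$x + 1L)] <- sums
  ion_image(values, target_mz = target_mz, tol_ppm = tol_ppm,
            normalization = normalization)
}

#' Hotspot removal by quantile clipping
#'
#' Values above the `high_quantile` quantile of the non-missing pixels
#' (linear-interpolation quantile, the default "type 7" rule) are set
#' equal to that quantile; everything else is untouched, so the
#' operation never increases a pixel. An image already clipped at the
#' same quantile is returned unchanged: the interpolated quantile of a
#' clipped image sits slightly below the original cut, so naively
#' re-clipping would keep shaving the top pixels — the recorded
#' `clipped_quantile` makes the operation idempotent instead.
#'
#' @param image An [ion_image()].
#' @param high_quantile Clipping quantile in (0, 1]; 0.99 is the
#'   conventional visualisation setting.
#' @return The clipped [ion_image()] with `clipped_quantile` recorded.
#' @export
hotspot_clip <- function(image, high_quantile = 0.99) {
  stopifnot(inherits(image, "ion_image"))
  if (high_quantile <= 0 || high_quantile > 1) {
    stop("high_quantile must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(image$clipped_quantile) &&
      isTRUE(image$clipped_quantile == high_quantile)) {
    return(image)
  }
  v <- image$values
  if (all(is.na(v))) stop("cannot clip an all-missing image", call. = FALSE)
  q <- stats::quantile(v, probs = high_quantile, na.rm = TRUE,
                       names = FALSE, type = 7)
  v[!is.na(v) & v > q] <- q
  image$values <- v
  image$clipped_quantile <- high_quantile
  image
}

#' Pixelwise ratio image
#'
#' The labelled-to-unlabelled visualisation: numerator divided by
#' denominator per pixel. Pixels where the denominator is zero, or
#' where either image is missing, are missing in the result. Both
#' inputs must carry the same normalisation state (the ratio cancels a
#' common TIC factor, but mixing normalised with raw images is a user
#' error).
#'
#' @param numerator,denominator [ion_image()]s of identical shape.
#' @return An [ion_image()] with `normalization = "denominator"`.
#' @export
ratio_image <- function(numerator, denominator) {
  stopifnot(inherits(numerator, "ion_image"), inherits(denominator, "ion_image"))
  if (!identical(dim(numerator$values), dim(denominator$values))) {
    stop("ratio_image: image shapes differ", call. = FALSE)
  }
  if (!identical(numerator$normalization, denominator$normalization)) {
    stop("ratio_image: images carry different normalization states", call. = FALSE)
  }
  den <- denominator$values
  den[!is.na(den) & den == 0] <- NA_real_
  out <- numerator$values / den
  ion_image(out, target_mz = numerator$target_mz, tol_ppm = numerator$tol_ppm,
            normalization = "denominator")
}

#' Region mask
#'
#' A boolean pixel selector with the same shape as the images it is
#' applied to.
#'
#' @param values Logical matrix (rows = y, columns = x).
#' @return A `region_mask` object.
#' @export
region_mask <- function(values) {
  stopifnot(is.matrix(values), is.logical(values))
  structure(list(values = values), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat("<region_mask> ", nrow(x$values), " x ", ncol(x$values), ", ",
      sum(x$values), " selected pixels\n", sep = "")
  invisible(x)
}

mask_values <- function(mask, shape = NULL) {
  v <- if (inherits(mask, "region_mask")) mask$values else mask
  stopifnot(is.matrix(v), is.logical(v))
  if (!is.null(shape) && !identical(dim(v), shape)) {
    stop("mask shape does not match image shape", call. = FALSE)
  }
  v
}

#' Multi-channel overlay of ion images
#'
#' Composes up to three ion images into an RGB overlay the way
#' multiplexed tracer figures are drawn: each image is hotspot-clipped
#' (default 99% quantile, skipped when the image is already clipped),
#' min-max scaled to [0, 1], and written into its colour channel.
#' Missing pixels contribute 0 to their channel.
#'
#' @param images List of 1-3 [ion_image()]s of identical shape.
#' @param colors Channel names, a permutation-subset of
#'   `c("red", "green", "blue")`, one per image.
#' @param clip_quantile Hotspot quantile applied to unclipped inputs.
#' @return An `msi_overlay`: list with `rgb`, an
#'   `n_rows x n_columns x 3` array in [0, 1], and `colors`.
#' @export
overlay_channels <- function(images, colors = c("red", "green", "blue"),
                             clip_quantile = 0.99) {
  if (inherits(images, "ion_image")) images <- list(images)
  if (length(images) < 1 || length(images) > 3) {
    stop("overlay supports 1 to 3 channels", call. = FALSE)
  }
  colors <- match.arg(colors, c("red", "green", "blue"), several.ok = TRUE)
  colors <- colors[seq_along(images)]
  if (anyDuplicated(colors)) stop("duplicate channel colours", call. = FALSE)
  shape <- dim(images[[1]]$values)
  rgb <- array(0, dim = c(shape, 3))
  channel_index <- c(red = 1L, green = 2L, blue = 3L)
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (!identical(dim(img$values), shape)) {
      stop("overlay images differ in shape", call. = FALSE)
    }
    if (is.null(img$clipped_quantile)) img <- hotspot_clip(img, clip_quantile)
    v <- img$values
    rng <- range(v, na.rm = TRUE)
    scaled <- if (diff(rng) > 0) (v - rng[1]) / diff(rng)
              else matrix(as.numeric(rng[1] > 0), nrow = shape[1], ncol = shape[2])
    scaled[is.na(scaled)] <- 0
    rgb[, , channel_index[[colors[i]]]] <- scaled
  }
  structure(list(rgb = rgb, colors = colors), class = "msi_overlay")
}

#' Plot an ion image
#' @param object An [ion_image()].
#' @param ... Unused.
#' @return A ggplot object (viridis-filled raster, image orientation).
#' @method autoplot ion_image
#' @export
autoplot.ion_image <- function(object, ...) {
  df <- as_tibble.ion_image(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = if (!is.na(object$target_mz))
      sprintf("m/z %.4f", object$target_mz) else "ratio") +
    ggplot2::theme_void()
}

#' Plot an RGB overlay
#' @param object An `msi_overlay` from [overlay_channels()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msi_overlay
#' @export
autoplot.msi_overlay <- function(object, ...) {
  d <- dim(object$rgb)
  df <- tibble::tibble(
    x = rep(seq_len(d[2]) - 1L, each = d[1]),
    y = rep(seq_len(d[1]) - 1L, times = d[2]),
    col = grDevices::rgb(as.vector(object$rgb[, , 1]),
                         as.vector(object$rgb[, , 2]),
                         as.vector(object$rgb[, , 3]))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$col)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
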