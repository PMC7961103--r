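#' Peak picking and ppm alignment across pixels
#'
#' Builds the dataset's feature table the way MSI software does after
#' lock-mass recalibration: per-pixel centroid peaks below the relative
#' intensity threshold (a fraction of the dataset base-peak intensity)
#' are discarded; the surviving peaks are clustered across pixels into
#' m/z features. Clusters are seeded greedily from the most intense
#' unassigned peak and collect every unassigned peak within
#' `align_tol_ppm` of the seed; each feature's consensus m/z is the
#' intensity-weighted mean of its member peaks. Features observed (with
#' nonzero intensity, after the intensity filter) in fewer than
#' `min_frequency` of the pixels are dropped. The defaults are the
#' standard MSI import settings: 0.05% relative intensity, 0.5% minimum
#' frequency, 3 ppm alignment tolerance.
#'
#' @param dataset An [msi_dataset()] (non-empty).
#' @param relative_intensity_threshold Fraction of the dataset base-peak
#'   intensity below which peaks are discarded.
#' @param min_frequency Minimum fraction of pixels in which a feature
#'   must be observed.
#' @param align_tol_ppm Clustering tolerance in ppm.
#' @return A `peak_table` object: list with `features` (tibble:
#'   `feature`, `mz`, `frequency`, `max_intensity`, `mean_intensity`),
#'   `values` (long tibble: `feature`, `pixel`, `intensity`),
#'   `n_pixels`, and `params`.
#' @export
pick_and_align_peaks <- function(dataset,
                                 relative_intensity_threshold = 0.0005,
                                 min_frequency = 0.005,
                                 align_tol_ppm = 3) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (n_pixels(dataset) == 0) stop("empty dataset", call. = FALSE)
  peaks <- as_tibble(dataset)
  if (nrow(peaks) == 0) stop("dataset contains no peaks", call. = FALSE)

  base_peak <- max(peaks$intensity)
  peaks <- peaks[peaks$intensity >= relative_intensity_threshold * base_peak, ]
  if (nrow(peaks) == 0) {
    stop("no peaks survive the relative intensity threshold", call. = FALSE)
  }

  cl <- cluster_peaks_greedy(peaks$mz, peaks$intensity, align_tol_ppm)
  peaks$feature_raw <- cl$assignment

  per_feature <- peaks |>
    dplyr::group_by(.data$feature_raw, .data$pixel) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")
  stats <- per_feature |>
    dplyr::group_by(.data$feature_raw) |>
    dplyr::summarise(
      n_px = dplyr::n(),
      max_intensity = max(.data$intensity),
      sum_intensity = sum(.data$intensity),
      .groups = "drop"
    )
  stats$mz <- cl$center[stats$feature_raw]
  stats$frequency <- stats$n_px / n_pixels(dataset)
  keep <- stats[stats$frequency >= min_frequency &
                  stats$max_intensity >= relative_intensity_threshold * base_peak, ]
  keep <- keep[order(keep$mz), ]
  if (nrow(keep) == 0) stop("no features pass the frequency filter", call. = FALSE)
  keep$feature <- seq_len(nrow(keep))

  values <- per_feature |>
    dplyr::inner_join(keep[c("feature_raw", "feature")], by = "feature_raw") |>
    dplyr::select("feature", "pixel", "intensity") |>
    dplyr::arrange(.data$feature, .data$pixel)

  features <- tibble::tibble(
    feature = keep$feature,
    mz = keep$mz,
    frequency = keep$frequency,
    max_intensity = keep$max_intensity,
    mean_intensity = keep$sum_intensity / n_pixels(dataset)
  )
  structure(list(
    features = features,
    values = tibble::as_tibble(values),
    n_pixels = n_pixels(dataset),
    params = list(relative_intensity_threshold = relative_intensity_threshold,
                  min_frequency = min_frequency,
                  align_tol_ppm = align_tol_ppm)
  ), class = "peak_table")
}

# Greedy intensity-ordered clustering: repeatedly seed a cluster at the
# most intense unassigned peak and capture all unassigned peaks within
# tol ppm of the seed. Returns per-peak cluster ids and the
# intensity-weighted consensus m/z per cluster. O(k log n) via a sorted
# m/z index, equivalent to the obvious O(n^2) procedure.
cluster_peaks_greedy <- function(mz, intensity, tol_ppm) {
  ord_mz <- order(mz)
  mz_s <- mz[ord_mz]
  int_s <- intensity[ord_mz]
  n <- length(mz_s)
  assignment <- integer(n)
  ord_int <- order(int_s, decreasing = TRUE)
  centers <- numeric(0)
  k <- 0L
  for (idx in ord_int) {
    if (assignment[idx] != 0L) next
    k <- k + 1L
    seed <- mz_s[idx]
    tol <- seed * tol_ppm * 1e-6
    lo <- findInterval(seed - tol, mz_s, left.open = TRUE) + 1L
    hi <- findInterval(seed + tol, mz_s)
    members <- lo:hi
    members <- members[assignment[members] == 0L]
    assignment[members] <- k
    centers[k] <- stats::weighted.mean(mz_s[members], int_s[members])
  }
  out <- integer(n)
  out[ord_mz] <- assignment
  list(assignment = out, center = centers)
}

#' @export
print.peak_table <- function(x, ...) {
  cat("<peak_table> ", nrow(x$features), " features over ", x$n_pixels,
      " pixels (thr ", x$params$relative_intensity_threshold * 100, "%, freq ",
      x$params$min_frequency * 100, "%, tol ", x$params$align_tol_ppm, " ppm)\n",
      sep = "")
  print(x$features, n = 10)
  invisible(x)
}

#' Mean spectrum over all pixels
#'
#' Per-feature mean intensity across every pixel of the dataset the
#' table was derived from, with pixels lacking the feature contributing
#' zero — the "averaged spectrum" view of an acquisition.
#'
#' @param dataset The [msi_dataset()] the peak table was derived from.
#' @param peak_table A [pick_and_align_peaks()] result.
#' @return A tibble with columns `mz` and `intensity`, class
#'   `mean_spectrum`.
#' @export
mean_spectrum <- function(dataset, peak_table) {
  stopifnot(inherits(peak_table, "peak_table"))
  sums <- peak_table$values |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(total = sum(.data$intensity), .groups = "drop")
  out <- dplyr::left_join(peak_table$features["feature"], sums, by = "feature")
  out$total[is.na(out$total)] <- 0
  res <- tibble::tibble(
    mz = peak_table$features$mz,
    intensity = out$total / peak_table$n_pixels
  )
  class(res) <- c("mean_spectrum", class(res))
  res
}

#' Stick plot of a mean spectrum
#' @param object A [mean_spectrum()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mean_spectrum
#' @export
autoplot.mean_spectrum <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0)) +
    ggplot2::labs(x = "m/z", y = "mean intensity") +
    ggplot2::theme_minimal()
}
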