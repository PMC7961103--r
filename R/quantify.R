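#' Tracer incorporation ratio over a region
#'
#' Mean and sample SD of the pixelwise labelled/unlabelled intensity
#' ratio over the masked region. Pixels where the unlabelled
#' (denominator) image is zero or either image is missing are excluded
#' — a zero denominator means the ratio is undefined there, not zero.
#' The statistic is invariant to any common positive rescaling of both
#' images (so it does not matter whether raw or identically
#' TIC-normalised images are supplied).
#'
#' @param labeled,unlabeled [ion_image()]s of identical shape.
#' @param mask Optional [region_mask()] (or logical matrix); defaults to
#'   all pixels.
#' @return A one-row tibble: `ratio_mean`, `ratio_sd`, `se`, `n`.
#' @export
incorporation_ratio <- function(labeled, unlabeled, mask = NULL) {
  stopifnot(inherits(labeled, "ion_image"), inherits(unlabeled, "ion_image"))
  if (!identical(dim(labeled$values), dim(unlabeled$values))) {
    stop("image shapes differ", call. = FALSE)
  }
  sel <- if (is.null(mask)) {
    matrix(TRUE, nrow(labeled$values), ncol(labeled$values))
  } else {
    mask_values(mask, dim(labeled$values))
  }
  num <- labeled$values[sel]
  den <- unlabeled$values[sel]
  ok <- !is.na(num) & !is.na(den) & den > 0
  if (!any(ok)) stop("no valid pixels under the mask", call. = FALSE)
  r <- num[ok] / den[ok]
  n <- length(r)
  s <- if (n > 1) stats::sd(r) else 0
  tibble::tibble(ratio_mean = mean(r), ratio_sd = s, se = s / sqrt(n), n = n)
}

#' Fold change of a signal between two regions
#'
#' Ratio of the image mean over region A to the mean over region B
#' (missing pixels excluded), with a delta-method standard error — the
#' "region-specific spectra" comparison used to quantify local
#' surfactant deposition.
#'
#' @param image An [ion_image()].
#' @param mask_a,mask_b Disjoint, non-empty [region_mask()]s (or logical
#'   matrices).
#' @return A one-row tibble: `fold`, `se`, `mean_a`, `mean_b`, `n_a`,
#'   `n_b`.
#' @export
region_fold_change <- function(image, mask_a, mask_b) {
  stopifnot(inherits(image, "ion_image"))
  a <- mask_values(mask_a, dim(image$values))
  b <- mask_values(mask_b, dim(image$values))
  if (!any(a) || !any(b)) stop("both regions must be non-empty", call. = FALSE)
  if (any(a & b)) stop("regions must be disjoint", call. = FALSE)
  va <- image$values[a]; va <- va[!is.na(va)]
  vb <- image$values[b]; vb <- vb[!is.na(vb)]
  if (length(va) == 0 || length(vb) == 0) {
    stop("a region contains no acquired pixels", call. = FALSE)
  }
  mb <- mean(vb)
  if (mb == 0) stop("zero mean signal in the reference region", call. = FALSE)
  ma <- mean(va)
  fold <- ma / mb
  # delta method on the ratio of two independent means
  se <- fold * sqrt(stats::var(va) / (length(va) * ma^2) +
                    stats::var(vb) / (length(vb) * mb^2))
  tibble::tibble(fold = fold, se = se, mean_a = ma, mean_b = mb,
                 n_a = length(va), n_b = length(vb))
}

#' Remodeling-product abundances relative to the administered dose
#'
#' Expresses each labelled species' per-sample intensity as a
#' percentage of the tracer signal at administration (`t0_value`), then
#' averages across samples — the analysis shape behind
#' "relative abundance (% of the dose at 0 h), mean +/- SD, n per
#' group".
#'
#' @param table Long intensity table: tibble/data frame with columns
#'   `species`, `sample`, `intensity` (non-negative).
#' @param dose_reference Name of the administered tracer species (used
#'   to tag the reference row; it must be present in `table`).
#' @param t0_value The reference intensity at time zero (> 0), on the
#'   same scale as `intensity`.
#' @return A tibble with one row per species: `species`,
#'   `rel_abundance_mean` (percent of t0), `rel_abundance_sd` (sample
#'   SD), `se`, `n`, `is_reference`.
#' @export
remodeling_abundances <- function(table, dose_reference, t0_value) {
  stopifnot(all(c("species", "sample", "intensity") %in% names(table)))
  if (t0_value <= 0) stop("t0_value must be positive", call. = FALSE)
  if (any(table$intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (!dose_reference %in% table$species) {
    stop("dose_reference species not found in the table", call. = FALSE)
  }
  tibble::as_tibble(table) |>
    dplyr::mutate(rel = .data$intensity / t0_value * 100) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      rel_abundance_mean = mean(.data$rel),
      rel_abundance_sd = if (dplyr::n() > 1) stats::sd(.data$rel) else 0,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(se = .data$rel_abundance_sd / sqrt(.data$n),
                  is_reference = .data$species == dose_reference) |>
    dplyr::select("species", "rel_abundance_mean", "rel_abundance_sd",
                  "se", "n", "is_reference")
}

#' Two-sample Student's t-test between groups
#'
#' The classical pooled-variance two-tailed Student's t-test (set
#' `var_equal = FALSE` for the Welch variant) used for per-species group
#' comparisons of tracer abundances.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances (classical Student's test,
#'   the default) or not (Welch).
#' @return A `tracer_ttest` object; see [tidy()] and [glance()].
#' @export
group_compare <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  ht <- stats::t.test(values_a, values_b, var.equal = var_equal,
                      alternative = "two.sided")
  structure(list(
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value,
    estimate_a = mean(values_a),
    estimate_b = mean(values_b),
    n_a = length(values_a),
    n_b = length(values_b),
    var_equal = var_equal,
    htest = ht
  ), class = "tracer_ttest")
}

#' @export
print.tracer_ttest <- function(x, ...) {
  cat("<tracer_ttest> ", if (x$var_equal) "Student" else "Welch",
      " two-sample, two-sided\n", sep = "")
  cat(sprintf("  t = %.4f, df = %.2f, p = %.4g\n", x$t, x$df, x$p))
  cat(sprintf("  group means: %.4g (n=%d) vs %.4g (n=%d)\n",
              x$estimate_a, x$n_a, x$estimate_b, x$n_b))
  invisible(x)
}

#' @rdname group_compare
#' @param x A `tracer_ttest` object.
#' @param ... Unused.
#' @method tidy tracer_ttest
#' @export
tidy.tracer_ttest <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate_a - x$estimate_b,
    estimate_a = x$estimate_a,
    estimate_b = x$estimate_b,
    statistic = x$t,
    p_value = x$p,
    df = x$df,
    conf_low = x$htest$conf.int[1],
    conf_high = x$htest$conf.int[2],
    method = if (x$var_equal) "Student two-sample t" else "Welch two-sample t"
  )
}

#' @rdname group_compare
#' @method glance tracer_ttest
#' @export
glance.tracer_ttest <- function(x, ...) {
  tibble::tibble(statistic = x$t, df = x$df, p_value = x$p,
                 n_a = x$n_a, n_b = x$n_b)
}
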