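#' Configure a synthetic lung-section phantom
#'
#' The phantom emulates the measured structure of a dual-tracer lung
#' MSI acquisition with known ground truth: a parenchyma background
#' over the whole grid, circular bronchiole cross-sections carrying the
#' polyunsaturated species, and an elliptical surfactant-deposition
#' blob where exogenous DPPC (partly universally 13C-labelled) has
#' accumulated. Labelled isotopologues ride on their parent species:
#' methyl-D9 PC32:0 at `d9_fraction` of the endogenous PC32:0 signal
#' (newly synthesised PC), the acyl-remodelling product
#' 13C24-PC16:0_20:4 at `c24_fraction` of the total PC32:0 signal
#' (parenchyma only), and U13C-DPPC at `u13c_enrichment` of the
#' deposited (exogenous) PC32:0. Each species pixel receives one shared
#' multiplicative log-normal noise draw (`noise_cv`) that all of its
#' adducts, isotopologues and derived label signals inherit — MALDI
#' shot-to-shot variability acts on the ablated material as a whole —
#' plus a smaller independent per-peak detection noise
#' (`peak_noise_cv`, default 2%, the order of Orbitrap centroid
#' intensity repeatability; keeping it small ensures the pixelwise
#' labelled/unlabelled ratio estimator stays unbiased relative to its
#' standard error). Per-spectrum mass-calibration drift is linear in
#' acquisition index, spanning `-drift_ppm` to `+drift_ppm`.
#'
#' @param grid_shape `c(n_columns, n_rows)`; 64 x 64 keeps a full
#'   pipeline run in seconds.
#' @param pixel_size_um Pixel edge (micrometres).
#' @param species_panel Data frame with columns `species` (PC name),
#'   `parenchyma`, `bronchiole` (relative abundances >= 0).
#' @param adduct_ratios Named vector of H/Na/K ionisation ratios.
#' @param d9_fraction Labelled fraction of endogenous PC32:0
#'   (default 1%).
#' @param c24_fraction Remodelling product as fraction of total PC32:0
#'   (default 0.1%).
#' @param u13c_enrichment Universally labelled fraction of the
#'   deposited exogenous DPPC (default 7.55%, the enrichment of the
#'   porcine-derived therapeutic surfactant; the synthetic-surfactant
#'   alternative is 2.87%).
#' @param deposition_enhancement Total PC32:0 enhancement factor inside
#'   the deposition blob (default 2.5, the centre of the observed
#'   2-3 fold range).
#' @param envelope_depth Isotopologue peaks generated per ion (M+0 ...).
#' @param noise_cv Shared per-species-pixel log-normal CV (default 0.2).
#' @param peak_noise_cv Independent per-peak log-normal CV.
#' @param drift_ppm Calibration drift amplitude in ppm; must stay below
#'   `lock_search_tol_ppm`.
#' @param lock_search_tol_ppm Lock-mass search tolerance the drift must
#'   respect.
#' @param seed Integer seed; the generator is bit-reproducible given
#'   the seed, which is recorded in the output metadata.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(grid_shape = c(64, 64),
                           pixel_size_um = 40,
                           species_panel = default_species_panel(),
                           adduct_ratios = c(H = 0.3, Na = 1, K = 0.25),
                           d9_fraction = 0.01,
                           c24_fraction = 0.001,
                           u13c_enrichment = 0.0755,
                           deposition_enhancement = 2.5,
                           envelope_depth = 3,
                           noise_cv = 0.2,
                           peak_noise_cv = 0.02,
                           drift_ppm = 3,
                           lock_search_tol_ppm = 20,
                           seed = 1L) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 4))
  stopifnot(all(c("species", "parenchyma", "bronchiole") %in% names(species_panel)))
  if (any(species_panel$parenchyma < 0) || any(species_panel$bronchiole < 0)) {
    stop("species abundances must be non-negative", call. = FALSE)
  }
  if (!"PC32:0" %in% species_panel$species) {
    stop("the panel must contain PC32:0 (the tracer parent species)", call. = FALSE)
  }
  for (f in c(d9_fraction, c24_fraction, u13c_enrichment)) {
    if (f < 0 || f > 1) stop("labelled fractions must lie in [0, 1]", call. = FALSE)
  }
  if (deposition_enhancement < 1) {
    stop("deposition_enhancement must be >= 1", call. = FALSE)
  }
  if (drift_ppm >= lock_search_tol_ppm) {
    stop("drift amplitude must stay below the lock-mass search tolerance",
         call. = FALSE)
  }
  if (!setequal(names(adduct_ratios), c("H", "Na", "K"))) {
    stop("adduct_ratios must be named H, Na, K", call. = FALSE)
  }
  structure(list(
    grid_shape = as.integer(grid_shape), pixel_size_um = pixel_size_um,
    species_panel = tibble::as_tibble(species_panel),
    adduct_ratios = adduct_ratios[c("H", "Na", "K")],
    d9_fraction = d9_fraction, c24_fraction = c24_fraction,
    u13c_enrichment = u13c_enrichment,
    deposition_enhancement = deposition_enhancement,
    envelope_depth = as.integer(envelope_depth),
    noise_cv = noise_cv, peak_noise_cv = peak_noise_cv,
    drift_ppm = drift_ppm, lock_search_tol_ppm = lock_search_tol_ppm,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' @rdname phantom_config
#' @export
default_species_panel <- function() {
  tibble::tibble(
    species = c("PC32:0", "PC32:1", "PC34:1", "PC36:4", "PC38:6"),
    parenchyma = c(100, 60, 40, 0, 0),
    bronchiole = c(30, 25, 40, 50, 30)
  )
}

# bronchioles: two circular cross-sections; deposition: one ellipse in
# the parenchyma, disjoint from the bronchioles by construction
phantom_masks <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]
  xs <- matrix(rep(seq_len(nx) - 1L, each = ny), nrow = ny)
  ys <- matrix(rep(seq_len(ny) - 1L, times = nx), nrow = ny)
  sc <- min(nx, ny)
  disk <- function(cx, cy, r) {
    ((xs - cx * nx)^2 + (ys - cy * ny)^2) <= (r * sc)^2
  }
  bronchiole <- disk(0.25, 0.30, 0.09) | disk(0.70, 0.65, 0.08)
  ellipse <- (((xs - 0.65 * nx) / (0.16 * sc))^2 +
              ((ys - 0.22 * ny) / (0.11 * sc))^2) <= 1
  deposition <- ellipse & !bronchiole
  parenchyma <- !bronchiole
  list(parenchyma = parenchyma, bronchiole = bronchiole,
       deposition = deposition,
       background = parenchyma & !deposition)
}

lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sigma^2 / 2, sd = sigma))
}

#' Generate a lung-phantom MSI dataset with ground truth
#'
#' Renders the configured phantom into an [msi_dataset()] of per-pixel
#' centroid spectra (species x adducts x natural-abundance
#' isotopologue envelopes from the mass engine, plus the labelled
#' ions), together with the complete ground truth needed to score any
#' downstream pipeline stage. Deterministic given `config$seed`.
#'
#' @param config A [phantom_config()].
#' @return A list with elements `dataset` (an [msi_dataset()]) and
#'   `truth` (a list: `masks` — parenchyma / bronchiole / deposition /
#'   background [region_mask()]s; `species_maps` — per-species noised
#'   intensity matrices; `fractions`; `drift_ppm_per_pixel`; `ion_table`
#'   — the generated theoretical ions; `config`).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  nx <- config$grid_shape[1]; ny <- config$grid_shape[2]
  n_px <- nx * ny
  masks <- phantom_masks(config$grid_shape)
  # acquisition order: row-major (x fastest), matching stage rastering
  px <- rep(seq_len(nx) - 1L, times = ny)
  py <- rep(seq_len(ny) - 1L, each = nx)
  at <- function(m) m[cbind(py + 1L, px + 1L)]  # matrix -> acquisition vector

  panel <- config$species_panel
  bron <- at(masks$bronchiole)
  depo <- at(masks$deposition)

  # noise-free per-pixel abundance pools
  pools <- list()
  for (i in seq_len(nrow(panel))) {
    sp <- panel$species[i]
    base <- ifelse(bron, panel$bronchiole[i], panel$parenchyma[i])
    if (sp == "PC32:0") {
      deposited <- ifelse(depo, base * (config$deposition_enhancement - 1), 0)
      pools[[sp]] <- list(endogenous = base, deposited = deposited)
    } else {
      pools[[sp]] <- list(endogenous = base, deposited = rep(0, n_px))
    }
  }

  # one shared noise draw per (species, pixel); labelled derivatives of a
  # species inherit it so that labelled fractions are exact per pixel
  species_amount <- list()
  for (sp in names(pools)) {
    L <- lognormal_noise(n_px, config$noise_cv)
    species_amount[[sp]] <- list(
      total = (pools[[sp]]$endogenous + pools[[sp]]$deposited) * L,
      endogenous = pools[[sp]]$endogenous * L,
      deposited = pools[[sp]]$deposited * L
    )
  }

  paren <- at(masks$parenchyma)
  amount <- list()
  for (sp in names(species_amount)) amount[[sp]] <- species_amount[[sp]]$total
  amount[["D9-PC32:0"]] <- config$d9_fraction * species_amount[["PC32:0"]]$endogenous
  amount[["U13C-PC32:0"]] <- config$u13c_enrichment * species_amount[["PC32:0"]]$deposited
  amount[["13C24-PC16:0_20:4"]] <-
    config$c24_fraction * species_amount[["PC32:0"]]$total * as.numeric(paren)

  # theoretical ion table: species x adduct x isotopologue peak
  ion_rows <- list()
  for (sp_name in names(amount)) {
    sp <- parse_species(sp_name)
    env <- isotopologue_envelope(sp$formula, config$envelope_depth)
    nm <- monoisotopic_mass(sp$formula)
    for (ad in names(config$adduct_ratios)) {
      ion_rows[[length(ion_rows) + 1]] <- tibble::tibble(
        species = sp_name, adduct = ad, peak = env$peak,
        mz = adduct_mz(nm, ad) + env$mass_offset,
        scale = config$adduct_ratios[[ad]] * env$relative_abundance
      )
    }
  }
  ion_table <- dplyr::bind_rows(ion_rows)
  ord <- order(ion_table$mz)
  ion_table <- ion_table[ord, ]

  n_ions <- nrow(ion_table)
  base_int <- matrix(0, nrow = n_px, ncol = n_ions)
  for (j in seq_len(n_ions)) {
    base_int[, j] <- amount[[ion_table$species[j]]] * ion_table$scale[j]
  }
  peak_noise <- matrix(lognormal_noise(n_px * n_ions, config$peak_noise_cv),
                       nrow = n_px)
  inten <- base_int * peak_noise

  drift <- if (n_px > 1) {
    config$drift_ppm * (2 * (seq_len(n_px) - 1) / (n_px - 1) - 1)
  } else rep(0, n_px)

  mz0 <- ion_table$mz
  mz_list <- vector("list", n_px)
  int_list <- vector("list", n_px)
  for (i in seq_len(n_px)) {
    keep <- inten[i, ] > 0
    mzs <- mz0[keep] * (1 + drift[i] * 1e-6)
    ints <- inten[i, keep]
    # merge any coincident theoretical m/z (distinct ions are > 1e-3 apart
    # in the default panel; this guards user panels)
    if (length(mzs) > 1 && any(diff(mzs) < 1e-6)) {
      grp <- cumsum(c(TRUE, diff(mzs) >= 1e-6))
      ints <- as.numeric(tapply(ints, grp, sum))
      mzs <- as.numeric(tapply(mzs, grp, function(v) v[1]))
    }
    mz_list[[i]] <- mzs
    int_list[[i]] <- ints
  }

  dataset <- msi_dataset(
    tibble::tibble(x = px, y = py, mz = mz_list, intensity = int_list),
    grid_shape = config$grid_shape,
    pixel_size_um = config$pixel_size_um,
    metadata = list(source = "pctracer phantom", seed = config$seed,
                    drift_ppm = config$drift_ppm)
  )

  to_map <- function(v) {
    m <- matrix(NA_real_, nrow = ny, ncol = nx)
    m[cbind(py + 1L, px + 1L)] <- v
    m
  }
  truth <- list(
    masks = lapply(masks, region_mask),
    species_maps = lapply(amount, to_map),
    fractions = list(d9_fraction = config$d9_fraction,
                     c24_fraction = config$c24_fraction,
                     u13c_enrichment = config$u13c_enrichment,
                     deposition_enhancement = config$deposition_enhancement),
    drift_ppm_per_pixel = drift,
    ion_table = ion_table,
    config = config
  )
  list(dataset = dataset, truth = truth)
}

#' Generate a shotgun-lipidomics phantom table
#'
#' Emulates the per-animal labelled-PC profiles of a macrophage
#' remodelling experiment: per-sample species intensities drawn
#' log-normally (multiplicative CV `cv`, mean preserved) around the
#' configured group means expressed as percent of the tracer dose at
#' time zero. With `cv = 0` every sample equals its group mean.
#'
#' @param n_per_group Samples per group (>= 2; the reference design
#'   uses 8 animals).
#' @param group_means Named vector of species means, in percent of the
#'   administered tracer at t = 0.
#' @param cv Multiplicative coefficient of variation across samples.
#' @param t0_value Intensity assigned to 100% (the dose at t = 0).
#' @param seed Integer seed.
#' @return A list with `table` (long tibble: `species`, `sample`,
#'   `intensity`) and `truth` (the generating parameters).
#' @export
generate_shotgun_profiles <- function(n_per_group = 8,
                                      group_means = c(
                                        "U13C-PC32:0" = 38.7,
                                        "13C24-PC16:0_20:4" = 36.8,
                                        "13C24-PC16:0_22:6" = 24.5),
                                      cv = 0.2, t0_value = 100, seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  rows <- lapply(names(group_means), function(sp) {
    tibble::tibble(
      species = sp,
      sample = paste0("animal", seq_len(n_per_group)),
      intensity = group_means[[sp]] / 100 * t0_value *
        lognormal_noise(n_per_group, cv)
    )
  })
  list(
    table = dplyr::bind_rows(rows),
    truth = list(group_means = group_means, cv = cv,
                 t0_value = t0_value, n_per_group = n_per_group, seed = seed)
  )
}
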