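#' Monoisotopic mass of a formula
#'
#' Sum of per-isotope monoisotopic masses from the package's atomic-mass
#' table (AME2020). Deterministic; the empty formula has mass 0.
#'
#' @param formula An [elemental_formula()], a formula string, or a
#'   [lipid_species()].
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(pc_sum_formula(32, 0))  # 733.562156
#' @export
monoisotopic_mass <- function(formula) {
  formula <- as_formula(formula)
  if (length(formula) == 0) return(0)
  sum(ISOTOPE_MASS[names(formula)] * unclass(formula))
}

as_formula <- function(x) {
  if (inherits(x, "elemental_formula")) x
  else if (inherits(x, "lipid_species")) x$formula
  else if (is.character(x)) parse_formula(x)
  else stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
            " as an elemental formula", call. = FALSE)
}

#' m/z of a singly charged cationic adduct
#'
#' Adds the adduct atom's mass and subtracts one electron mass, the
#' convention confirmed by the lock-mass value of sodiated dipalmitoyl
#' PC (756.551374).
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (or an
#'   [elemental_formula()] / [lipid_species()], whose mass is taken).
#' @param adduct One of `"H"`, `"Na"`, `"K"`.
#' @return Theoretical m/z of the +1 cation.
#' @examples
#' adduct_mz(pc_sum_formula(32, 0), "Na")  # 756.551376
#' @export
adduct_mz <- function(neutral_mass, adduct = c("Na", "H", "K")) {
  adduct <- match.arg(adduct)
  if (inherits(neutral_mass, "elemental_formula") ||
      inherits(neutral_mass, "lipid_species") || is.character(neutral_mass)) {
    neutral_mass <- monoisotopic_mass(neutral_mass)
  }
  if (any(neutral_mass < 0)) stop("neutral mass must be non-negative", call. = FALSE)
  neutral_mass + ADDUCT_DELTA[[adduct]]
}

#' Signed parts-per-million mass error
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z (> 0).
#' @return `(observed - theoretical) / theoretical * 1e6`, vectorised.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive", call. = FALSE)
  (observed - theoretical) / theoretical * 1e6
}

#' Resolving power needed to separate two peaks
#'
#' The full-width-at-half-maximum criterion: R = mean(m/z) / |difference|.
#'
#' @param mz_a,mz_b The two m/z values (must differ).
#' @return Dimensionless resolving power.
#' @examples
#' resolving_power_required(765.6079, 765.5989)
#' @export
resolving_power_required <- function(mz_a, mz_b) {
  if (any(mz_a == mz_b)) {
    stop("peaks at identical m/z cannot be resolved by resolving power", call. = FALSE)
  }
  ((mz_a + mz_b) / 2) / abs(mz_a - mz_b)
}

#' Theoretical ion table for a set of species
#'
#' Convenience wrapper producing a tidy table of theoretical m/z values
#' for one or more species across adducts — the working currency of
#' image extraction and annotation.
#'
#' @param species A [lipid_species()], species name string, or list of
#'   either.
#' @param adducts Character vector of adducts (subset of H, Na, K).
#' @return A tibble with columns `species`, `formula`, `neutral_mass`,
#'   `adduct`, `mz`.
#' @examples
#' species_mz_table(c("PC32:0", "D9-PC32:0"), adducts = "Na")
#' @export
species_mz_table <- function(species, adducts = c("H", "Na", "K")) {
  if (inherits(species, "lipid_species") || is.character(species) && length(species) == 1) {
    species <- list(species)
  }
  species <- lapply(species, function(s) if (is.character(s)) parse_species(s) else s)
  rows <- lapply(species, function(sp) {
    nm <- monoisotopic_mass(sp$formula)
    tibble::tibble(
      species = format(sp),
      formula = format(sp$formula),
      neutral_mass = nm,
      adduct = adducts,
      mz = vapply(adducts, function(a) adduct_mz(nm, a), numeric(1))
    )
  })
  dplyr::bind_rows(rows)
}
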