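# PC headgroup fragment chemistry. Sodiated/potassiated PC precursors
# fragment by two characteristic headgroup neutral losses:
#   trimethylamine  N(CH3)3   C3H9N     (nominal 59)
#   phosphocholine  C5H14NO4P           (nominal 183)
# Protonated PC gives the phosphocholine headgroup cation C5H15NO4P+
# (nominal 184) instead, the basis of precursor-ion scans.
TMA_FORMULA <- c(C = 3L, H = 9L, N = 1L)
PCHOL_FORMULA <- c(C = 5L, H = 14L, N = 1L, O = 4L, P = 1L)

# How many label atoms travel with each headgroup loss, per label name.
# The choline headgroup holds 5 carbons (3 of them N-methyl) and, for
# methyl-D9 choline, all 9 deuteriums; chain labels (the remaining 19 of
# a 13C24 palmitoyl-lyso label, or the acyl carbons of a universal
# label) stay on the charged fragment.
LABEL_ROUTING <- list(
  "D9"    = list(tma = c(n13C = 0L, nD = 9L), pchol = c(n13C = 0L, nD = 9L)),
  "13C5"  = list(tma = c(n13C = 3L, nD = 0L), pchol = c(n13C = 5L, nD = 0L)),
  "13C24" = list(tma = c(n13C = 3L, nD = 0L), pchol = c(n13C = 5L, nD = 0L)),
  "U13C"  = list(tma = c(n13C = 3L, nD = 0L), pchol = c(n13C = 5L, nD = 0L))
)

#' Predict label-aware PC MS/MS fragments
#'
#' For sodiated and potassiated precursors, predicts the two headgroup
#' neutral losses (trimethylamine and phosphocholine) with the label
#' atoms routed into the loss according to where the label resides; for
#' protonated precursors, predicts the diagnostic phosphocholine
#' headgroup cation (nominal 184 unlabelled, 193 for methyl-D9, 189 for
#' a 13C5 headgroup). Fragment names follow the field's
#' loss-nomenclature style, annotating heavy atoms in the loss and its
#' integer nominal mass, e.g. `-N(CH3)3(59)` or `-PC(+[13]C5)(188)`.
#'
#' @param species A [lipid_species()] or species name string (see
#'   [parse_species()]).
#' @param adduct One of `"Na"`, `"K"`, `"H"`.
#' @param routing Optional label routing for label names not built in: a
#'   list with elements `tma` and `pchol`, each `c(n13C = , nD = )`
#'   giving the heavy atoms leaving with that loss.
#' @return A tibble with columns `name`, `type`, `loss_formula`,
#'   `loss_mass`, `loss_nominal`, `precursor_mz`, `fragment_mz`,
#'   `carries_label`.
#' @examples
#' predict_pc_fragments("13C24-PC16:0_20:4", adduct = "Na")
#' predict_pc_fragments("D9-PC32:0", adduct = "H")
#' @export
predict_pc_fragments <- function(species, adduct = c("Na", "K", "H"),
                                 routing = NULL) {
  if (is.character(species)) species <- parse_species(species)
  stopifnot(inherits(species, "lipid_species"))
  adduct <- match.arg(adduct)
  label <- species$label
  if (is.null(routing)) {
    routing <- if (is_unlabeled(label)) {
      list(tma = c(n13C = 0L, nD = 0L), pchol = c(n13C = 0L, nD = 0L))
    } else {
      r <- LABEL_ROUTING[[label$name]]
      if (is.null(r)) {
        stop("no built-in label routing for label '", label$name,
             "'; supply `routing`", call. = FALSE)
      }
      r
    }
  }
  precursor_mz <- adduct_mz(monoisotopic_mass(species$formula), adduct)

  cnt <- function(v, s) if (s %in% names(v)) v[[s]] else 0L
  labeled_loss <- function(base, route) {
    if (route[["n13C"]] > cnt(base, "C") || route[["nD"]] > cnt(base, "H")) {
      stop("label routing exceeds the atoms in the neutral loss", call. = FALSE)
    }
    f <- elemental_formula(counts = base)
    apply_label(f, label_spec(route[["n13C"]], route[["nD"]]))
  }
  loss_row <- function(loss_formula, base_name, route) {
    lm <- monoisotopic_mass(loss_formula)
    nominal <- as.integer(round(lm))
    carries <- route[["n13C"]] > 0 || route[["nD"]] > 0
    annot <- if (route[["n13C"]] > 0) paste0("(+[13]C", route[["n13C"]], ")")
             else if (route[["nD"]] > 0) paste0("(+D", route[["nD"]], ")")
             else ""
    tibble::tibble(
      name = paste0("-", base_name, annot, "(", nominal, ")"),
      type = "neutral_loss",
      loss_formula = format(loss_formula),
      loss_mass = lm,
      loss_nominal = nominal,
      precursor_mz = precursor_mz,
      fragment_mz = precursor_mz - lm,
      carries_label = carries
    )
  }

  if (adduct %in% c("Na", "K")) {
    dplyr::bind_rows(
      loss_row(labeled_loss(TMA_FORMULA, routing$tma), "N(CH3)3", routing$tma),
      loss_row(labeled_loss(PCHOL_FORMULA, routing$pchol), "PC", routing$pchol)
    )
  } else {
    # protonated PC: the charge stays on the phosphocholine headgroup
    hg <- labeled_loss(PCHOL_FORMULA, routing$pchol)
    cation_mz <- adduct_mz(monoisotopic_mass(hg), "H")
    nominal <- as.integer(round(cation_mz))
    tibble::tibble(
      name = paste0("PC-head(", nominal, ")"),
      type = "headgroup_cation",
      loss_formula = format(hg),
      loss_mass = NA_real_,
      loss_nominal = nominal,
      precursor_mz = precursor_mz,
      fragment_mz = cation_mz,
      carries_label = routing$pchol[["n13C"]] > 0 || routing$pchol[["nD"]] > 0
    )
  }
}

#' Annotate a measured MS/MS spectrum with fragment predictions
#'
#' For each prediction, the most intense centroid peak within the
#' closed, symmetric `tol_ppm` window around the theoretical fragment
#' m/z is matched and its signed ppm error reported. Predictions
#' without an in-window peak are returned with `NA` observations.
#'
#' @param peaks A centroided spectrum: tibble/data frame with columns
#'   `mz`, `intensity` (e.g. from [read_peaklist()]).
#' @param predictions A [predict_pc_fragments()] table.
#' @param tol_ppm Match tolerance in ppm.
#' @return The predictions tibble with added columns `observed_mz`,
#'   `observed_intensity`, `ppm` and `matched`.
#' @export
annotate_msms <- function(peaks, predictions, tol_ppm = 5) {
  stopifnot(all(c("mz", "intensity") %in% names(peaks)),
            all(c("name", "fragment_mz") %in% names(predictions)))
  mz <- peaks$mz
  int <- peaks$intensity
  match_one <- function(target) {
    tol <- target * tol_ppm * 1e-6
    in_win <- which(mz >= target - tol & mz <= target + tol)
    if (length(in_win) == 0) return(c(NA_real_, NA_real_))
    best <- in_win[which.max(int[in_win])]
    c(mz[best], int[best])
  }
  hits <- vapply(predictions$fragment_mz, match_one, numeric(2))
  out <- predictions
  out$observed_mz <- hits[1, ]
  out$observed_intensity <- hits[2, ]
  out$ppm <- ifelse(is.na(out$observed_mz), NA_real_,
                    ppm_error(out$observed_mz, out$fragment_mz))
  out$matched <- !is.na(out$observed_mz)
  out
}
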