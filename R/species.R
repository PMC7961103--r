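#' Specify a stable-isotope label
#'
#' A label is a count of carbon-12 to carbon-13 substitutions and of
#' hydrogen to deuterium substitutions, plus a free-text name. The names
#' used throughout pulmonary-surfactant tracing are `"D9"` (methyl-D9
#' choline, nine deuteriums on the three N-methyl groups), `"13C5"`
#' (fully labelled choline headgroup), `"13C24"` (a labelled palmitoyl
#' chain retained from hydrolysed, universally labelled DPPC plus the
#' labelled headgroup), and `"U13C"` (every carbon labelled).
#'
#' @param n13C Number of carbons substituted with 13C.
#' @param nD Number of hydrogens substituted with deuterium.
#' @param name Label name; used to route label atoms into MS/MS neutral
#'   losses (see [predict_pc_fragments()]).
#' @return A `label_spec` object. `label_spec(0, 0)` is the unlabelled
#'   identity.
#' @examples
#' label_spec(nD = 9, name = "D9")
#' label_spec(n13C = 24, name = "13C24")
#' @export
label_spec <- function(n13C = 0, nD = 0, name = NULL) {
  if (n13C < 0 || nD < 0 || n13C != round(n13C) || nD != round(nD)) {
    stop("label counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(name)) {
    name <- if (n13C == 0 && nD == 0) "unlabeled"
            else if (nD > 0 && n13C == 0) paste0("D", nD)
            else if (n13C > 0 && nD == 0) paste0("13C", n13C)
            else paste0("13C", n13C, "-D", nD)
  }
  structure(list(n13C = as.integer(n13C), nD = as.integer(nD), name = name),
            class = "label_spec")
}

#' @export
format.label_spec <- function(x, ...) {
  if (x$n13C == 0 && x$nD == 0) "unlabeled" else x$name
}

#' @export
print.label_spec <- function(x, ...) {
  cat("<label_spec> ", format(x), " (13C: ", x$n13C, ", D: ", x$nD, ")\n", sep = "")
  invisible(x)
}

is_unlabeled <- function(label) label$n13C == 0 && label$nD == 0

#' Elemental formula of a diacyl phosphatidylcholine sum composition
#'
#' For a diacyl PC with `total_carbons` acyl carbons (n) and
#' `double_bonds` acyl double bonds (d), the neutral molecule is
#' C(n+8) H(2n+16-2d) N O8 P: the glycerophosphocholine backbone
#' contributes 8 carbons and the headgroup nitrogen, and each double
#' bond removes two hydrogens.
#'
#' @param total_carbons Total acyl carbons across both chains (>= 2).
#' @param double_bonds Total acyl double bonds (>= 0, chemically
#'   feasible for the chain length).
#' @return An [elemental_formula()].
#' @examples
#' pc_sum_formula(32, 0)  # dipalmitoyl PC: C40H80NO8P
#' pc_sum_formula(36, 4)  # C44H80NO8P
#' @export
pc_sum_formula <- function(total_carbons, double_bonds) {
  if (total_carbons < 2 || total_carbons != round(total_carbons)) {
    stop("invalid PC species: total acyl carbons must be an integer >= 2", call. = FALSE)
  }
  if (double_bonds < 0 || double_bonds != round(double_bonds)) {
    stop("invalid PC species: double bonds must be a non-negative integer", call. = FALSE)
  }
  # each acyl chain of c carbons supports at most floor((c-1)/2) cis double
  # bonds; for the sum composition the bound is on the pooled carbons
  max_db <- max(0, floor((total_carbons - 2) / 2))
  if (double_bonds > max_db) {
    stop("invalid PC species: ", double_bonds, " double bonds is infeasible for ",
         total_carbons, " acyl carbons", call. = FALSE)
  }
  elemental_formula(
    C = total_carbons + 8,
    H = 2 * total_carbons + 16 - 2 * double_bonds,
    N = 1, O = 8, P = 1
  )
}

#' Substitute labelled isotopes into a formula
#'
#' Moves `n13C` counts from C to 13C and `nD` counts from H to D. Total
#' atom counts are conserved; only the isotopic identity changes.
#'
#' @param formula An [elemental_formula()].
#' @param label A [label_spec()].
#' @return The labelled [elemental_formula()].
#' @examples
#' apply_label(pc_sum_formula(32, 0), label_spec(nD = 9, name = "D9"))
#' @export
apply_label <- function(formula, label) {
  stopifnot(inherits(label, "label_spec"))
  nC <- formula_count(formula, "C")
  nH <- formula_count(formula, "H")
  if (label$n13C > nC) {
    stop("label overflow: ", label$n13C, " 13C substitutions but only ",
         nC, " carbons available", call. = FALSE)
  }
  if (label$nD > nH) {
    stop("label overflow: ", label$nD, " D substitutions but only ",
         nH, " hydrogens available", call. = FALSE)
  }
  counts <- unclass(formula)
  counts["C"] <- nC - label$n13C
  counts["H"] <- nH - label$nD
  counts <- c(counts, "13C" = label$n13C, "D" = label$nD)
  elemental_formula(counts = counts)
}

#' Define a phosphatidylcholine species
#'
#' Species are identified at sum-composition level (`PC36:4`) or
#' chain-resolved level (`PC16:0_20:4` when the sn-position is unknown,
#' `PC16:0/20:4` when it is known), optionally carrying a stable-isotope
#' label.
#'
#' @param total_carbons Total acyl carbons; may be omitted when `chains`
#'   is given.
#' @param double_bonds Total acyl double bonds; may be omitted when
#'   `chains` is given.
#' @param chains Optional list of two `c(carbons, double_bonds)` pairs.
#' @param sn_defined Whether the chain positions are resolved
#'   (rendered with `/` instead of `_`).
#' @param label A [label_spec()]; defaults to unlabelled.
#' @return A `lipid_species` object.
#' @examples
#' lipid_species(32, 0)
#' lipid_species(chains = list(c(16, 0), c(20, 4)), label = label_spec(n13C = 24, name = "13C24"))
#' @export
lipid_species <- function(total_carbons = NULL, double_bonds = NULL,
                          chains = NULL, sn_defined = FALSE,
                          label = label_spec()) {
  if (!is.null(chains)) {
    stopifnot(is.list(chains), length(chains) == 2)
    cs <- vapply(chains, function(ch) ch[[1]], numeric(1))
    ds <- vapply(chains, function(ch) ch[[2]], numeric(1))
    if (is.null(total_carbons)) total_carbons <- sum(cs)
    if (is.null(double_bonds)) double_bonds <- sum(ds)
    if (sum(cs) != total_carbons || sum(ds) != double_bonds) {
      stop("chain compositions must sum to the species totals", call. = FALSE)
    }
  }
  if (is.null(total_carbons) || is.null(double_bonds)) {
    stop("either totals or chains must be supplied", call. = FALSE)
  }
  formula <- pc_sum_formula(total_carbons, double_bonds)  # validates feasibility
  structure(list(
    lipid_class = "PC",
    total_carbons = as.integer(total_carbons),
    total_double_bonds = as.integer(double_bonds),
    chains = chains,
    sn_defined = isTRUE(sn_defined),
    label = label,
    formula = apply_label(formula, label)
  ), class = "lipid_species")
}

#' Parse a PC species name such as "PC32:0", "PC16:0_20:4" or "PC16:0/20:4"
#'
#' @param x Species name string, optionally prefixed with a label as in
#'   `"D9-PC32:0"`, `"U13C-PC32:0"`, `"13C24-PC16:0_20:4"` or
#'   `"13C5-PC34:1"`.
#' @return A [lipid_species()].
#' @export
parse_species <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  s <- x
  label <- label_spec()
  universal <- FALSE
  if (grepl("^[^-]+-PC", s)) {
    lab_name <- sub("-PC.*$", "", s)
    s <- sub("^[^-]+-", "", s)
    if (lab_name == "U13C") {
      universal <- TRUE
    } else {
      label <- switch(lab_name,
        "D9" = label_spec(nD = 9, name = "D9"),
        "13C5" = label_spec(n13C = 5, name = "13C5"),
        "13C24" = label_spec(n13C = 24, name = "13C24"),
        stop("unknown label prefix '", lab_name, "'; construct the species with ",
             "lipid_species() and an explicit label_spec()", call. = FALSE)
      )
    }
  }
  body <- sub("^PC", "", s)
  if (!grepl("^PC", s)) stop("only PC species are supported: ", x, call. = FALSE)
  if (grepl("[_/]", body)) {
    sep <- if (grepl("/", body)) "/" else "_"
    parts <- strsplit(body, sep, fixed = TRUE)[[1]]
    chains <- lapply(parts, function(p) as.integer(strsplit(p, ":")[[1]]))
    sp <- lipid_species(chains = chains, sn_defined = sep == "/", label = label)
  } else {
    nd <- as.integer(strsplit(body, ":")[[1]])
    sp <- lipid_species(nd[1], nd[2], label = label)
  }
  if (universal) sp <- u13c_species(sp)
  sp
}

# special-case constructor: universally 13C-labelled species (all carbons)
#' Universally 13C-labelled variant of a species
#' @param species A [lipid_species()] (unlabelled).
#' @return The same species with every carbon substituted to 13C.
#' @export
u13c_species <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  n_carbon <- formula_count(species$formula, "C") + formula_count(species$formula, "13C")
  lipid_species(species$total_carbons, species$total_double_bonds,
                chains = species$chains, sn_defined = species$sn_defined,
                label = label_spec(n13C = n_carbon, name = "U13C"))
}

#' @export
format.lipid_species <- function(x, ...) {
  body <- if (!is.null(x$chains)) {
    sep <- if (x$sn_defined) "/" else "_"
    paste0("PC", paste(vapply(x$chains, function(ch)
      paste0(ch[[1]], ":", ch[[2]]), character(1)), collapse = sep))
  } else {
    paste0("PC", x$total_carbons, ":", x$total_double_bonds)
  }
  if (is_unlabeled(x$label)) body else paste0(format(x$label), "-", body)
}

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species> ", format(x), "  [", format(x$formula), "]\n", sep = "")
  invisible(x)
}
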