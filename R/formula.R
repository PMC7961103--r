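#' Construct an elemental formula
#'
#' An elemental formula is a named count vector over the element and
#' isotope symbols the package supports (`C`, `13C`, `H`, `D`, `N`, `O`,
#' `P`, `Na`, `K`). Heavy-isotope symbols are first-class citizens so
#' that stable-isotope labels are represented structurally rather than
#' as mass offsets.
#'
#' @param ... Named integer counts, e.g. `elemental_formula(C = 40, H = 80, N = 1, O = 8, P = 1)`.
#' @param counts Alternatively, a named numeric vector of counts.
#' @return An object of class `elemental_formula`: a named integer
#'   vector of non-negative counts.
#' @examples
#' elemental_formula(C = 40, H = 80, N = 1, O = 8, P = 1)
#' @export
elemental_formula <- function(..., counts = NULL) {
  x <- if (is.null(counts)) c(...) else counts
  if (length(x) == 0) {
    out <- integer(0)
    names(out) <- character(0)
    return(structure(out, class = "elemental_formula"))
  }
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("all formula counts must be named with element or isotope symbols", call. = FALSE)
  }
  unknown <- setdiff(names(x), names(ISOTOPE_MASS))
  if (length(unknown) > 0) {
    stop("unsupported element or isotope symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(x < 0) || any(x != round(x))) {
    stop("formula counts must be non-negative integers", call. = FALSE)
  }
  x <- tapply(as.integer(round(x)), names(x), sum)
  x <- x[x > 0]
  sym <- intersect(names(ISOTOPE_MASS), names(x))
  out <- as.integer(x[sym])
  names(out) <- sym
  structure(out, class = "elemental_formula")
}

#' @export
format.elemental_formula <- function(x, ...) {
  if (length(x) == 0) return("(empty)")
  n <- unclass(x)
  # render heavy isotopes first (13C24C20H80NO8P style), then CHNOP order
  order_sym <- c("13C", "C", "D", "H", "N", "O", "P", "Na", "K")
  n <- n[intersect(order_sym, names(n))]
  paste0(mapply(function(sym, cnt) {
    paste0(sym, if (cnt > 1) cnt else "")
  }, names(n), n), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format(x),
      "  (", sprintf("%.6f", monoisotopic_mass(x)), " Da)\n", sep = "")
  invisible(x)
}

#' @export
`+.elemental_formula` <- function(e1, e2) {
  elemental_formula(counts = c(unclass(e1), unclass(e2)))
}

#' Count lookup on a formula
#'
#' @param formula An [elemental_formula()].
#' @param symbol Element or isotope symbol.
#' @return Integer count (0 when absent).
#' @export
formula_count <- function(formula, symbol) {
  n <- unname(unclass(formula)[symbol])
  ifelse(is.na(n), 0L, as.integer(n))
}

#' Parse a formula string such as "C40H80NO8P" or "13C24C20H80NO8P"
#'
#' @param x A single formula string. Heavy isotopes are written with the
#'   mass number prefix (`13C`, or `D` for deuterium).
#' @return An [elemental_formula()].
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  s <- gsub("\\s", "", x)
  if (s == "" || s == "(empty)") return(elemental_formula())
  m <- gregexpr("(13C|D|Na|K|C|H|N|O|P)([0-9]*)", s)[[1]]
  toks <- regmatches(s, gregexpr("(13C|D|Na|K|C|H|N|O|P)([0-9]*)", s))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("cannot parse formula string: ", x, call. = FALSE)
  }
  sym <- sub("^(13C|D|Na|K|C|H|N|O|P).*$", "\\1", toks)
  cnt <- sub("^(13C|D|Na|K|C|H|N|O|P)", "", toks)
  cnt <- ifelse(cnt == "", 1L, as.integer(cnt))
  names(cnt) <- sym
  elemental_formula(counts = cnt)
}
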