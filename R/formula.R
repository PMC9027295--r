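#' Parse a chemical formula string
#'
#' Parses a plain elemental composition such as `"C42H81O8NP"` into a named
#' integer vector of atom counts. Element symbols are one capital letter
#' optionally followed by one lowercase letter; each symbol may be followed by
#' an integer count (default 1). Symbols may repeat ("CH3CH3" is C2H6) and
#' order is irrelevant. Only elements present in the built-in isotope table
#' (C, H, N, O, P, S) are accepted; isotope-labelled notation (e.g. "D" for
#' deuterium) is rejected.
#'
#' Formulas here denote the ion as measured: adducts are included in the
#' composition and a single charge is assumed, so "protonated PC 34:2" is
#' written `C42H81O8NP` (the extra H of the adduct already counted).
#'
#' @param text formula string, e.g. `"C42H81O8NP"`. An empty string is the
#'   empty formula (all counts zero).
#' @return an object of class `chem_formula`: a named integer vector of
#'   per-element atom counts, in Hill order (C, H, then alphabetical).
#' @examples
#' parse_formula("C42H81O8NP")
#' parse_formula("C3H5O2N")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  counts <- integer(0)
  if (nzchar(text)) {
    m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
    tokens <- regmatches(text, list(m))[[1]]
    if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(text)) {
      stop("malformed formula: '", text, "'", call. = FALSE)
    }
    for (tok in tokens) {
      sym <- sub("[0-9]*$", "", tok)
      num <- substr(tok, nchar(sym) + 1L, nchar(tok))
      if (!sym %in% supported_elements()) {
        stop("unknown element symbol '", sym, "' in formula '", text, "'",
             call. = FALSE)
      }
      n <- if (nzchar(num)) {
        if (grepl("^0", num)) {
          stop("zero or zero-prefixed count for '", sym, "' in '", text, "'",
               call. = FALSE)
        }
        as.integer(num)
      } else 1L
      counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
    }
  }
  new_chem_formula(counts)
}

new_chem_formula <- function(counts) {
  counts <- counts[counts != 0L]
  if (any(counts < 0L)) stop("negative atom count", call. = FALSE)
  # Hill order: C first, H second, remaining elements alphabetical
  syms <- names(counts)
  rest <- sort(setdiff(syms, c("C", "H")))
  ord <- c(intersect(c("C", "H"), syms), rest)
  structure(as.integer(counts[ord]), names = ord, class = "chem_formula")
}

#' Coerce to a chemical formula
#'
#' @param x a `chem_formula`, a formula string, or a named numeric vector of
#'   atom counts.
#' @return a `chem_formula`
#' @export
as_chem_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  if (is.character(x)) return(parse_formula(x))
  if (is.numeric(x) && !is.null(names(x))) {
    if (any(x != round(x)) || any(x < 0)) {
      stop("atom counts must be nonnegative integers", call. = FALSE)
    }
    bad <- setdiff(names(x), supported_elements())
    if (length(bad)) stop("unknown element symbol: ", bad[1], call. = FALSE)
    return(new_chem_formula(stats::setNames(as.integer(x), names(x))))
  }
  stop("cannot coerce to chem_formula", call. = FALSE)
}

#' Write a formula in Hill order
#'
#' Canonical writer: `format_formula(parse_formula(x))` round-trips any valid
#' input up to canonical ordering.
#'
#' @param f a `chem_formula`
#' @return a string such as `"C42H81NO8P"` (Hill order; count 1 omitted)
#' @export
format_formula <- function(f) {
  f <- as_chem_formula(f)
  if (!length(f)) return("")
  paste0(names(f), ifelse(unclass(f) == 1L, "", unclass(f)), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.chem_formula <- function(x, ...) format_formula(x)

#' Add two formulas elementwise
#' @param a,b formulas (any form accepted by [as_chem_formula()])
#' @return a `chem_formula`
#' @export
formula_add <- function(a, b) {
  a <- as_chem_formula(a); b <- as_chem_formula(b)
  syms <- union(names(a), names(b))
  cnt <- stats::setNames(integer(length(syms)), syms)
  cnt[names(a)] <- cnt[names(a)] + unclass(a)
  cnt[names(b)] <- cnt[names(b)] + unclass(b)
  new_chem_formula(cnt)
}

#' Subtract formula `b` from formula `a` elementwise
#'
#' Used to derive the neutral fragment from precursor and product ion
#' (constant-product transitions) or the product ion from precursor and
#' neutral loss (constant-neutral-loss transitions). Any element going
#' negative signals an inconsistent library row.
#'
#' @param a,b formulas; `b` must be an elementwise sub-formula of `a`
#' @return a `chem_formula` (possibly empty)
#' @export
formula_subtract <- function(a, b) {
  a <- as_chem_formula(a); b <- as_chem_formula(b)
  syms <- union(names(a), names(b))
  cnt <- stats::setNames(integer(length(syms)), syms)
  cnt[names(a)] <- cnt[names(a)] + unclass(a)
  cnt[names(b)] <- cnt[names(b)] - unclass(b)
  if (any(cnt < 0L)) {
    stop("formula subtraction went negative for element(s): ",
         paste(syms[cnt < 0L], collapse = ", "),
         " (fragment is not a sub-formula of the precursor)", call. = FALSE)
  }
  new_chem_formula(cnt)
}

#' Monoisotopic mass of a formula
#'
#' Sum of lightest-isotope masses in Da. Electron mass is ignored (singly
#' charged ions assumed); intended for library sanity checks against declared
#' Q1/Q3 values, not for exact-mass work.
#'
#' @param f a formula
#' @return mass in Da (0 for the empty formula)
#' @export
monoisotopic_mass <- function(f) {
  f <- as_chem_formula(f)
  if (!length(f)) return(0)
  sum(unclass(f) * vapply(names(f), element_monoisotopic_mass, numeric(1)))
}
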