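# Embedded isotope table: CIAAW/IUPAC representative terrestrial abundances
# (2021 revision, rounded as commonly tabulated). Offsets are nucleon counts
# above the lightest (monoisotopic) isotope. For every supported element the
# offset-0 isotope is the most abundant, so aggregated patterns have p[1] as
# the base peak of the per-element distributions.
.isotope_table <- list(
  C = list(offset = c(0L, 1L), abundance = c(0.9893, 0.0107),
           mass0 = 12),
  H = list(offset = c(0L, 1L), abundance = c(0.999885, 0.000115),
           mass0 = 1.0078250319),
  N = list(offset = c(0L, 1L), abundance = c(0.99636, 0.00364),
           mass0 = 14.0030740052),
  O = list(offset = c(0L, 1L, 2L), abundance = c(0.99757, 0.00038, 0.00205),
           mass0 = 15.9949146221),
  P = list(offset = 0L, abundance = 1,
           mass0 = 30.97376151),
  S = list(offset = c(0L, 1L, 2L, 4L),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001),
           mass0 = 31.97207069)
)

#' Supported element symbols
#' @return character vector of the element symbols in the built-in table
#' @export
supported_elements <- function() names(.isotope_table)

#' The built-in isotope abundance table
#'
#' Per element: nucleon offsets above the monoisotopic isotope, fractional
#' abundances (summing to 1), and the monoisotopic mass. These are fixed,
#' versioned values (CIAAW representative abundances); all isotope-pattern
#' results in the package are deterministic functions of this table.
#'
#' @return named list with entries `offset`, `abundance`, `mass0` per element
#' @export
isotope_table <- function() .isotope_table

element_monoisotopic_mass <- function(sym) .isotope_table[[sym]]$mass0

# single-atom abundance vector indexed by nucleon offset 0..max offset
element_offset_vector <- function(sym) {
  e <- .isotope_table[[sym]]
  v <- numeric(max(e$offset) + 1L)
  v[e$offset + 1L] <- e$abundance
  v
}

# Truncated discrete convolution: (a * b)[0..max_order]. Offsets only add,
# so truncating intermediates never perturbs the retained prefix.
conv_trunc <- function(a, b, max_order) {
  out_len <- min(length(a) + length(b) - 1L, max_order + 1L)
  r <- numeric(out_len)
  for (k in seq_along(a)) {
    idx <- k:(k + length(b) - 1L)
    keep <- idx <= out_len
    if (!any(keep)) break
    r[idx[keep]] <- r[idx[keep]] + a[k] * b[keep]
  }
  r
}

# a^n under truncated convolution, by squaring
conv_pow <- function(a, n, max_order) {
  r <- 1
  b <- a
  while (n > 0L) {
    if (n %% 2L == 1L) r <- conv_trunc(r, b, max_order)
    n <- n %/% 2L
    if (n > 0L) b <- conv_trunc(b, b, max_order)
  }
  r
}

#' Aggregated isotopologue distribution of a formula
#'
#' Computes the nominal-mass (aggregated-by-nucleon-offset) isotopologue
#' distribution M0..Mn of an ion: per-element polynomial self-convolution
#' raised to the atom count, followed by cross-element convolution, truncated
#' at `max_order`. Aggregation by nucleon offset (rather than exact mass)
#' matches the unit-resolution behaviour of a triple quadrupole: all
#' isotopologues n nucleons above monoisotopic fall into one Q1/Q3 window.
#'
#' @param f a formula (string, named counts, or `chem_formula`)
#' @param max_order highest aggregate offset retained (default 10); tail
#'   probability mass beyond it is discarded, never renormalised
#' @return an `isotope_pattern`: list with `p` (absolute abundances, index
#'   `n+1` is Mn) and `r` (ratios to monoisotopic, `r[1] == 1`)
#' @examples
#' isotope_pattern("C42H81O8NP")$r[2]  # M1:M0 of protonated PC 34:2, ~0.47
#' @export
isotope_pattern <- function(f, max_order = 10L) {
  f <- as_chem_formula(f)
  stopifnot(length(max_order) == 1L, max_order >= 0)
  max_order <- as.integer(max_order)
  p <- 1
  for (sym in names(f)) {
    p <- conv_trunc(p, conv_pow(element_offset_vector(sym), f[[sym]], max_order), max_order)
  }
  length(p) <- max_order + 1L
  p[is.na(p)] <- 0
  structure(list(p = p, r = p / p[1L], max_order = max_order),
            class = "isotope_pattern")
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("<isotope_pattern> M0..M", x$max_order, "\n", sep = "")
  print(stats::setNames(signif(x$r, 3), paste0("M", seq_along(x$r) - 1L)))
  invisible(x)
}

#' Transition-level (MS2) isotopic distribution
#'
#' For an MRM transition A -> B, the signal of the (i, j) isotopologue pair
#' (precursor i nucleons and product j nucleons above monoisotopic, j <= i)
#' relative to the monoisotopic transition A0 -> B0 factorises over the two
#' independent moieties: `f(i, j) = r_NL[i - j] * r_B[j]`, where NL is the
#' neutral fragment `A - B` and B the product ion, and `r` are their
#' aggregated M:M0 abundance ratios. The library's MS2 formula is either the
#' product ion itself (`"ConstantProduct"`, e.g. phosphocholine m/z 184) or
#' the neutral loss (`"ConstantNeutralLoss"`, e.g. the 87 Da serine
#' fragment); the other moiety is derived by formula subtraction.
#'
#' @param precursor precursor-ion formula (adduct included)
#' @param ms2 product-ion or neutral-loss formula, per `ms2_mode`
#' @param ms2_mode `"ConstantProduct"` or `"ConstantNeutralLoss"`
#' @param max_order highest precursor isotopologue order (default 10)
#' @return a `transition_pattern`: list with `factors` (a lower-triangular
#'   `(max_order+1) x (max_order+1)` matrix, `factors[i+1, j+1] = f(i, j)`),
#'   the resolved `product` and `neutral_loss` formulas, and `ms2_mode`
#' @examples
#' tp <- transition_pattern("C42H81O8NP", "C5H15O4NP", "ConstantProduct")
#' tp$factors[2, 1]  # f(1, 0) ~ 0.41
#' @export
transition_pattern <- function(precursor, ms2,
                               ms2_mode = c("ConstantProduct", "ConstantNeutralLoss"),
                               max_order = 10L) {
  ms2_mode <- match.arg(ms2_mode)
  precursor <- as_chem_formula(precursor)
  ms2 <- as_chem_formula(ms2)
  if (ms2_mode == "ConstantProduct") {
    product <- ms2
    neutral_loss <- formula_subtract(precursor, product)
  } else {
    neutral_loss <- ms2
    product <- formula_subtract(precursor, neutral_loss)
  }
  r_nl <- isotope_pattern(neutral_loss, max_order)$r
  r_b <- isotope_pattern(product, max_order)$r
  n <- max_order + 1L
  fct <- matrix(0, n, n)
  for (i in 0:max_order) {
    for (j in 0:i) fct[i + 1L, j + 1L] <- r_nl[i - j + 1L] * r_b[j + 1L]
  }
  structure(list(factors = fct, product = product, neutral_loss = neutral_loss,
                 ms2_mode = ms2_mode, max_order = max_order),
            class = "transition_pattern")
}

#' Extract a single transition factor f(i, j)
#' @param tp a `transition_pattern`
#' @param i precursor isotopologue order
#' @param j product isotopologue order (`j <= i`)
#' @return the factor, a nonnegative scalar; `f(0, 0)` is 1
#' @export
transition_factor <- function(tp, i, j) {
  stopifnot(inherits(tp, "transition_pattern"),
            i >= 0, i <= tp$max_order, j >= 0, j <= i)
  tp$factors[i + 1L, j + 1L]
}

#' @export
print.transition_pattern <- function(x, ...) {
  cat("<transition_pattern> ", x$ms2_mode,
      "; product ", format_formula(x$product),
      "; neutral loss ", format_formula(x$neutral_loss), "\n", sep = "")
  m <- min(4L, x$max_order)
  sub <- signif(x$factors[seq_len(m + 1L), seq_len(m + 1L), drop = FALSE], 2)
  dimnames(sub) <- list(paste0("i=", 0:m), paste0("j=", 0:m))
  print(sub)
  invisible(x)
}
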