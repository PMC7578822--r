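#' Titration mixture design
#'
#' Describes a titration design in which two reference RNA
#' samples A and B are mixed by mass into sample C (3 parts A : 1 part B) and
#' sample D (1 part A : 3 parts B).  Because the two references differ in
#' mRNA concentration, per-gene expression of the mixtures follows the
#' mRNA-corrected mixing law rather than the raw mass fractions; the
#' correction is the concentration ratio `z` = [mRNA in A] / [mRNA in B].
#' The multipliers `a` (upper) and `b` (lower) widen comparisons of
#' single-replicate qPCR measurements to absorb their typical ~15%
#' coefficient of variation.
#'
#' @param c_fraction_a Mass fraction of sample A in mixture C (default 3/4).
#' @param d_fraction_a Mass fraction of sample A in mixture D (default 1/4).
#' @param z mRNA concentration ratio A/B (default 1.43).
#' @param a Upper margin multiplier (default 1.15).
#' @param b Lower margin multiplier (default 0.85).
#'
#' @return An object of class `mixture_design`.
#' @examples
#' d <- mixture_design()
#' mixture_expression(8, 4, mixture_design(z = 1))
#' @export
mixture_design <- function(c_fraction_a = 0.75, d_fraction_a = 0.25,
                           z = 1.43, a = 1.15, b = 0.85) {
  stopifnot(is.numeric(c_fraction_a), length(c_fraction_a) == 1L,
            c_fraction_a > 0, c_fraction_a < 1,
            is.numeric(d_fraction_a), length(d_fraction_a) == 1L,
            d_fraction_a > 0, d_fraction_a < 1)
  if (!is.numeric(z) || length(z) != 1L || z <= 0)
    stop("'z' must be a single positive number")
  if (!is.numeric(a) || !is.numeric(b) || b <= 0 || b > 1 || a < 1)
    stop("margins must satisfy 0 < b <= 1 <= a")
  structure(list(c_fraction_a = c_fraction_a,
                 d_fraction_a = d_fraction_a,
                 z = z, a = a, b = b),
            class = "mixture_design")
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf(paste0("Titration mixture design: C = %.2fA + %.2fB, ",
                     "D = %.2fA + %.2fB\n  z = %.3f, margins a = %.3f, b = %.3f\n"),
              x$c_fraction_a, 1 - x$c_fraction_a,
              x$d_fraction_a, 1 - x$d_fraction_a, x$z, x$a, x$b))
  invisible(x)
}

#' Expected expression of the titration mixtures
#'
#' Computes the per-mRNA-normalized expected expression of mixtures C and D
#' from the expression of a gene in the pure reference samples A and B.  With
#' the default 3:1 / 1:3 mass fractions the law is
#' `C = (3 z A + B) / (3 z + 1)` and `D = (z A + 3 B) / (z + 3)`, which for
#' `z = 1` reduces to the plain weighted means `C = 0.75 A + 0.25 B` and
#' `D = 0.25 A + 0.75 B`, and whose ratio `C/D` reproduces
#' [emr_expected()] for any `z`.
#'
#' @param expr_a,expr_b Non-negative expression of the gene in samples A and B
#'   (vectors recycled to common length).
#' @param design A [mixture_design()].
#'
#' @return A list with numeric vectors `c` and `d`.
#' @export
mixture_expression <- function(expr_a, expr_b, design = mixture_design()) {
  stopifnot(inherits(design, "mixture_design"))
  if (any(expr_a < 0) || any(expr_b < 0))
    stop("expression values must be non-negative")
  z <- design$z
  # mass fraction p of A contributes p*z mRNA parts against (1-p) parts of B
  wc <- design$c_fraction_a * z / (design$c_fraction_a * z + (1 - design$c_fraction_a))
  wd <- design$d_fraction_a * z / (design$d_fraction_a * z + (1 - design$d_fraction_a))
  list(c = wc * expr_a + (1 - wc) * expr_b,
       d = wd * expr_a + (1 - wd) * expr_b)
}

#' Expected mixing ratio (EMR) of samples C and D
#'
#' Given a gene's expression ratio `R = A/B` between the two reference
#' samples, returns the expected ratio of its expression in the 3:1 and 1:3
#' mixtures, corrected for the mRNA concentration ratio `z`:
#' `EMR = (3 z R + 1) / (z R + 3) * (z + 3) / (3 z + 1)`.
#' The EMR is monotone increasing in `R` and bounded between
#' `(z + 3) / (3 (3 z + 1))` and `3 (z + 3) / (3 z + 1)`.
#'
#' @param r_ab Positive A/B expression ratio (vectorized).
#' @param z Positive mRNA concentration ratio A/B (default 1.43).
#'
#' @return Numeric vector of expected C/D ratios.
#' @examples
#' emr_expected(1)            # == 1
#' emr_expected(3, z = 1)     # 5/3
#' @export
emr_expected <- function(r_ab, z = 1.43) {
  if (any(!is.finite(r_ab)) || any(r_ab <= 0))
    stop("'r_ab' must be positive and finite")
  if (!is.numeric(z) || length(z) != 1L || z <= 0)
    stop("'z' must be a single positive number")
  (3 * z * r_ab + 1) / (z * r_ab + 3) * (z + 3) / (3 * z + 1)
}
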