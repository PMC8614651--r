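# Mutation-pressure versus selection diagnostics: PR2 bias coordinates,
# the GC12-on-GC3 neutrality regression, and the ENC-ratio histogram.

#' Parity-rule-2 bias coordinates
#'
#' The PR2 plot places each gene at (`gc_bias`, `at_bias`) =
#' (G3/(G3+C3), A3/(A3+T3)); (0.5, 0.5) indicates no strand-asymmetric
#' bias between the complementary bases at the third codon position. By
#' default the biases use the third-position bases of all sense codons; a
#' fourfold-only restriction is available via
#' [third_position_fractions()].
#'
#' @param profile A `composition_profile`, or any list with fields `a3`,
#'   `t3`, `g3`, `c3`.
#' @return A `pr2_point`: list with `at_bias`, `gc_bias` and `defined`
#'   (FALSE, with `NA` coordinates, when a denominator is zero).
#' @export
#' @examples
#' pr2_point(list(a3 = 0.3, t3 = 0.1, g3 = 0.4, c3 = 0.2))
pr2_point <- function(profile) {
  a3 <- profile$a3; t3 <- profile$t3; g3 <- profile$g3; c3 <- profile$c3
  stopifnot(is.numeric(a3), is.numeric(t3), is.numeric(g3), is.numeric(c3))
  at_den <- a3 + t3
  gc_den <- g3 + c3
  at_bias <- if (is.finite(at_den) && at_den > 0) a3 / at_den else NA_real_
  gc_bias <- if (is.finite(gc_den) && gc_den > 0) g3 / gc_den else NA_real_
  structure(list(at_bias = at_bias, gc_bias = gc_bias,
                 defined = !is.na(at_bias) && !is.na(gc_bias)),
            class = "pr2_point")
}

#' Neutrality-plot regression of GC12 on GC3
#'
#' Ordinary least squares of `p12` (mean G+C at codon positions 1 and 2)
#' on `p3` (GC3) across genes, with the Pearson correlation and its
#' two-sided p-value. A slope near 1 indicates that directional mutation
#' pressure acts on all codon positions alike (complete neutrality); a
#' slope near 0 indicates that selection holds first/second positions
#' constant while GC3 drifts.
#'
#' @param p3 Numeric vector of GC3 values (>= 3 points, non-constant).
#' @param p12 Numeric vector of GC12 values, same length.
#' @return A `neutrality_fit`: list with `slope`, `intercept`, `r`,
#'   `p_value`, `n`. `r`/`p_value` are `NA` when `p12` is constant.
#' @export
neutrality_fit <- function(p3, p12) {
  stopifnot(is.numeric(p3), is.numeric(p12), length(p3) == length(p12))
  n <- length(p3)
  if (n < 3L) stop("neutrality fit needs at least 3 points")
  if (stats::sd(p3) == 0) stop("neutrality fit undefined: p3 has zero variance")
  fit <- stats::lm(p12 ~ p3)
  if (stats::sd(p12) == 0) {
    r <- NA_real_
    p <- NA_real_
  } else {
    ct <- stats::cor.test(p3, p12, method = "pearson")
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = r, p_value = p, n = n),
            class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf("<neutrality_fit> slope = %.4f, intercept = %.4f, r = %s, p = %s, n = %d\n",
              x$slope, x$intercept, format(x$r), format(x$p_value), x$n))
  invisible(x)
}

#' Histogram of ENC ratios
#'
#' Bins `(ENC_expected - ENC_observed) / ENC_expected` values into
#' half-open bins `[edge, edge + width)` whose edges are aligned so that 0
#' is always an edge, making the under-/over-prediction split visible.
#'
#' @param ratios Non-empty numeric vector of ENC ratios.
#' @param bin_width Positive bin width (default 0.05).
#' @return An `enc_ratio_histogram`: list with `bin_edges` (length
#'   `bins + 1`), `bin_counts`, `n`.
#' @export
enc_ratio_histogram <- function(ratios, bin_width = 0.05) {
  ratios <- as.numeric(ratios)
  if (length(ratios) == 0L) stop("no ratios to bin")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  if (any(!is.finite(ratios))) stop("ratios must be finite")
  # small tolerance so values sitting exactly on an edge go to the upper bin
  lo <- floor(min(ratios) / bin_width + 1e-9)
  hi <- floor(max(ratios) / bin_width + 1e-9)
  idx <- floor(ratios / bin_width + 1e-9) - lo + 1L
  structure(list(bin_edges = (lo:(hi + 1L)) * bin_width,
                 bin_counts = tabulate(idx, nbins = hi - lo + 1L),
                 n = length(ratios)),
            class = "enc_ratio_histogram")
}
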