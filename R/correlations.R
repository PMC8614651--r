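# Correlation battery: Spearman/Pearson cells with significance flags,
# per-group correlation matrices over composition metrics, and the
# per-codon RSCU-versus-GC3 correlation table behind the usual heatmap.

sig_stars <- function(p) {
  if (is.na(p)) "undefined" else if (p < 0.01) "p<0.01" else if (p < 0.05) "p<0.05" else "ns"
}

#' Correlation between two metric vectors
#'
#' Spearman rank correlation (average ranks for ties; exact p-value for
#' n <= 10 without ties, t-approximation otherwise) or Pearson
#' product-moment correlation, both with two-sided p-values. Zero variance
#' in either argument yields a flagged-undefined cell rather than an
#' error.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A `correlation_cell`: list with `r`, `p_value`, `n`, `method`,
#'   `significance` (`"p<0.01"`, `"p<0.05"`, `"ns"` or `"undefined"`) and
#'   `defined`.
#' @export
#' @examples
#' cor_cell(1:4, c(2, 1, 4, 3))$r  # 0.6
cor_cell <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("correlation needs at least 3 paired observations")
  undefined <- if (method == "pearson") {
    stats::sd(x) == 0 || stats::sd(y) == 0
  } else {
    stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0
  }
  if (undefined) {
    return(structure(list(r = NA_real_, p_value = NA_real_, n = n,
                          method = method, significance = "undefined",
                          defined = FALSE),
                     class = "correlation_cell"))
  }
  if (method == "spearman") {
    has_ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman",
                      exact = (n <= 10L && !has_ties)))
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
  }
  p <- min(ct$p.value, 1)
  structure(list(r = unname(ct$estimate), p_value = p, n = n,
                 method = method, significance = sig_stars(p),
                 defined = TRUE),
            class = "correlation_cell")
}

#' @rdname cor_cell
#' @export
spearman_cor <- function(x, y) cor_cell(x, y, "spearman")

#' @rdname cor_cell
#' @export
pearson_cor <- function(x, y) cor_cell(x, y, "pearson")

#' Standard metric-pair sets for the correlation battery
#'
#' `nucleotide_pairs()`: overall A/T/G/C/GC fractions against the
#' corresponding third-position fractions. `enc_position_pairs()`: ENC
#' against GC1/GC2/GC3/GC12. `gc_position_pairs()`: overall GC against
#' the positional GC fractions.
#'
#' @return A `data.frame` with columns `x` and `y` naming metric columns.
#' @export
nucleotide_pairs <- function() {
  expand.grid(x = c("a_pct", "t_pct", "g_pct", "c_pct", "gc_pct"),
              y = c("a3", "t3", "g3", "c3", "gc3"),
              stringsAsFactors = FALSE)
}

#' @rdname nucleotide_pairs
#' @export
enc_position_pairs <- function() {
  data.frame(x = "enc_obs", y = c("p1", "p2", "p3", "p12"),
             stringsAsFactors = FALSE)
}

#' @rdname nucleotide_pairs
#' @export
gc_position_pairs <- function() {
  data.frame(x = "gc_pct", y = c("p1", "p2", "p3", "p12"),
             stringsAsFactors = FALSE)
}

#' Per-group correlation matrix over metric pairs
#'
#' @param metrics Per-sequence metric `data.frame` including a group
#'   column.
#' @param pairs `data.frame` with columns `x`, `y` naming metric columns
#'   (see [nucleotide_pairs()]).
#' @param method `"spearman"` or `"pearson"`.
#' @param group_col Name of the group column.
#' @return Long `data.frame`: `group`, `x`, `y`, `r`, `p_value`, `n`,
#'   `method`, `significance`. Groups with fewer than 3 sequences are
#'   skipped with a warning.
#' @export
correlation_matrix <- function(metrics, pairs, method = c("spearman", "pearson"),
                               group_col = "group") {
  method <- match.arg(method)
  stopifnot(is.data.frame(metrics), group_col %in% names(metrics),
            is.data.frame(pairs), all(c("x", "y") %in% names(pairs)))
  miss <- setdiff(unique(c(pairs$x, pairs$y)), names(metrics))
  if (length(miss) > 0L) {
    stop("metric column(s) not found: ", paste(miss, collapse = ", "))
  }
  out <- list()
  for (g in unique(metrics[[group_col]])) {
    df <- metrics[metrics[[group_col]] == g, , drop = FALSE]
    if (nrow(df) < 3L) {
      warning("group '", g, "' has fewer than 3 sequences; skipped")
      next
    }
    for (i in seq_len(nrow(pairs))) {
      cell <- cor_cell(df[[pairs$x[i]]], df[[pairs$y[i]]], method)
      out[[length(out) + 1L]] <- data.frame(
        group = g, x = pairs$x[i], y = pairs$y[i],
        r = cell$r, p_value = cell$p_value, n = cell$n,
        method = cell$method, significance = cell$significance,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(group = character(), x = character(), y = character(),
                      r = numeric(), p_value = numeric(), n = integer(),
                      method = character(), significance = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Per-codon correlation of RSCU with GC3
#'
#' For each group and each of the 59 synonymous codons, correlates the
#' codon's RSCU values across the group's sequences with their GC3. Codons
#' whose RSCU does not vary within a group are flagged `uniform` (no
#' correlation defined) — on a heatmap these are the blacked-out cells.
#'
#' @param rscu_mat Sequences-by-codon RSCU matrix (see [rscu_matrix()]).
#' @param gc3 Per-sequence GC3 vector, aligned with the matrix rows.
#' @param groups Per-sequence group labels, aligned with the matrix rows;
#'   a single label is recycled.
#' @param method `"spearman"` or `"pearson"`.
#' @return Long `data.frame`: `group`, `codon`, `r`, `p_value`, `n`,
#'   `flag` (`"ok"`, `"uniform"`), `significance`.
#' @export
rscu_gc3_correlation <- function(rscu_mat, gc3, groups = "all",
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  rscu_mat <- as.matrix(rscu_mat)
  if (length(groups) == 1L) groups <- rep(groups, nrow(rscu_mat))
  stopifnot(length(gc3) == nrow(rscu_mat), length(groups) == nrow(rscu_mat))
  out <- list()
  for (g in unique(groups)) {
    ix <- which(groups == g)
    if (length(ix) < 3L) {
      warning("group '", g, "' has fewer than 3 sequences; skipped")
      next
    }
    for (codon in colnames(rscu_mat)) {
      v <- rscu_mat[ix, codon]
      if (stats::sd(v) == 0) {
        out[[length(out) + 1L]] <- data.frame(
          group = g, codon = codon, r = NA_real_, p_value = NA_real_,
          n = length(ix), flag = "uniform", significance = "undefined",
          stringsAsFactors = FALSE)
        next
      }
      cell <- cor_cell(v, gc3[ix], method)
      out[[length(out) + 1L]] <- data.frame(
        group = g, codon = codon, r = cell$r, p_value = cell$p_value,
        n = cell$n, flag = "ok", significance = cell$significance,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
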