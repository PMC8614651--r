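# Correspondence analysis of the sequences-by-codon RSCU (or count) table,
# implemented directly as the SVD of the chi-square standardised residual
# matrix.

#' Correspondence analysis of a non-negative table
#'
#' Standard CA: the table is scaled to a correspondence matrix `P` with
#' row masses `r` and column masses `c`; the standardised residual matrix
#' `S = D_r^(-1/2) (P - r c') D_c^(-1/2)` is decomposed by SVD; principal
#' coordinates are the mass-rescaled singular vectors scaled by their
#' singular values. Total inertia equals the table's chi-square statistic
#' divided by its grand total, and axes are ordered by their inertia
#' share. All-zero columns are dropped with a warning (their position in
#' the chi-square metric is undefined); an all-zero row is an error.
#'
#' @param mat Non-negative numeric matrix (e.g. from [rscu_matrix()]),
#'   at least 2 rows.
#' @param n_axes Number of axes to report coordinates for (default 2,
#'   i.e. f1/f2). The full positive singular-value spectrum is always
#'   retained in the result.
#' @return A `coa_result`: list with `row_coords`, `col_coords` (principal
#'   coordinates, `n_axes` columns named `f1`, `f2`, ...),
#'   `singular_values`, `inertias` (fractions summing to 1),
#'   `total_inertia`, `row_masses`, `col_masses`. A rank-0 table (all rows
#'   proportional) yields zero coordinates and `total_inertia = 0`.
#' @export
#' @examples
#' m <- matrix(c(2, 0, 0, 2), 2, 2)
#' correspondence_analysis(m)$total_inertia  # 1
correspondence_analysis <- function(mat, n_axes = 2L) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("matrix must be numeric")
  if (any(!is.finite(mat)) || any(mat < 0)) {
    stop("matrix must be non-negative and finite")
  }
  if (nrow(mat) < 2L) stop("correspondence analysis needs at least 2 rows")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("row", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("col", seq_len(ncol(mat)))
  zero_col <- colSums(mat) == 0
  if (any(zero_col)) {
    warning("dropping all-zero column(s): ",
            paste(colnames(mat)[zero_col], collapse = ", "))
    mat <- mat[, !zero_col, drop = FALSE]
  }
  if (ncol(mat) < 2L) stop("need at least 2 non-zero columns")
  zero_row <- rowSums(mat) == 0
  if (any(zero_row)) {
    stop("all-zero row(s): ", paste(rownames(mat)[zero_row], collapse = ", "))
  }

  P <- mat / sum(mat)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  dec <- svd(S)
  keep <- dec$d > 1e-12 * max(1, dec$d[1L])
  d_pos <- dec$d[keep]
  total <- sum(d_pos^2)

  axis_names <- function(k) paste0("f", seq_len(k))
  if (length(d_pos) == 0L || total == 0) {
    rc <- matrix(0, nrow(mat), n_axes,
                 dimnames = list(rownames(mat), axis_names(n_axes)))
    cl <- matrix(0, ncol(mat), n_axes,
                 dimnames = list(colnames(mat), axis_names(n_axes)))
    return(structure(list(row_coords = rc, col_coords = cl,
                          singular_values = numeric(0),
                          inertias = numeric(0), total_inertia = 0,
                          row_masses = r, col_masses = cc),
                     class = "coa_result"))
  }

  nd <- min(n_axes, length(d_pos))
  sig <- d_pos[seq_len(nd)]
  rowc <- (dec$u[, seq_len(nd), drop = FALSE] / sqrt(r)) %*%
    diag(sig, nd, nd)
  colc <- (dec$v[, seq_len(nd), drop = FALSE] / sqrt(cc)) %*%
    diag(sig, nd, nd)
  dimnames(rowc) <- list(rownames(mat), axis_names(nd))
  dimnames(colc) <- list(colnames(mat), axis_names(nd))
  structure(list(row_coords = rowc, col_coords = colc,
                 singular_values = d_pos,
                 inertias = d_pos^2 / total, total_inertia = total,
                 row_masses = r, col_masses = cc),
            class = "coa_result")
}

#' @export
print.coa_result <- function(x, ...) {
  cat("<coa_result> ", nrow(x$row_coords), " rows x ", nrow(x$col_coords),
      " columns; total inertia ", format(x$total_inertia, digits = 6), "\n",
      sep = "")
  if (length(x$inertias) > 0L) {
    k <- min(4L, length(x$inertias))
    cat("  inertia fractions:",
        paste(sprintf("f%d=%.3f", seq_len(k), x$inertias[seq_len(k)]),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Mass-weighted group centroids on the CA axes
#'
#' @param result A `coa_result`.
#' @param groups Character vector of group labels, one per row of the
#'   analysed table, in row order.
#' @return Matrix of centroid coordinates, one row per group label.
#' @export
project_groups <- function(result, groups) {
  stopifnot(inherits(result, "coa_result"))
  groups <- as.character(groups)
  if (length(groups) != nrow(result$row_coords)) {
    stop("need exactly one group label per row")
  }
  if (anyNA(groups)) stop("unknown group label: NA")
  m <- result$row_masses
  cent <- lapply(split(seq_along(groups), groups), function(ix) {
    colSums(result$row_coords[ix, , drop = FALSE] * m[ix]) / sum(m[ix])
  })
  do.call(rbind, cent)
}
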