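# Effective number of codons (observed and GC3-expected) and relative
# synonymous codon usage.

#' Count sense codons
#'
#' Tabulates codon usage over the 61 sense codons. For a
#' `coding_sequence` the terminal stop codon is dropped first; for a raw
#' codon character vector any stop codons present are ignored.
#'
#' @param x A `coding_sequence` or character vector of codons.
#' @return Named integer vector over the 61 sense codons
#'   (class `codon_counts`).
#' @export
count_codons <- function(x) {
  codons <- if (inherits(x, "coding_sequence")) sense_of(x) else as.character(x)
  codons <- codons[!(codons %in% STOP_CODONS)]
  bad <- setdiff(unique(codons), SENSE_CODONS)
  if (length(bad) > 0L) {
    stop("not codons of the standard code: ", paste(bad, collapse = ", "))
  }
  tab <- table(factor(codons, levels = SENSE_CODONS))
  structure(stats::setNames(as.integer(tab), SENSE_CODONS),
            class = "codon_counts")
}

as_codon_counts <- function(counts) {
  if (inherits(counts, "coding_sequence")) return(count_codons(counts))
  counts <- unclass(counts)
  if (is.null(names(counts))) stop("counts must be named by codon")
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be non-negative and finite")
  }
  full <- stats::setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  keep <- intersect(names(counts), SENSE_CODONS)
  full[keep] <- counts[keep]
  full
}

#' Pool codon count tables
#'
#' @param ... `codon_counts` vectors (or anything [count_codons()] accepts).
#' @return Elementwise sum as a `codon_counts` vector.
#' @export
pool_counts <- function(...) {
  tabs <- lapply(list(...), as_codon_counts)
  structure(Reduce(`+`, tabs), class = "codon_counts")
}

# Wright's per-family homozygosity: F = (n * sum(p^2) - 1) / (n - 1).
# Returns NA for families with fewer than 2 codons observed.
family_homozygosity <- function(counts, fam) {
  n <- sum(counts[fam])
  if (n < 2) return(NA_real_)
  p <- counts[fam] / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Observed effective number of codons (Wright's ENC)
#'
#' Wright's estimator on a codon count table. Per synonymous family the
#' homozygosity `F = (n * sum(p^2) - 1) / (n - 1)` is computed from the
#' within-family codon frequencies `p` and the family total `n`; families
#' with `n < 2` or `F <= 0` are excluded, and each usable `F` is floored at
#' `1/k` (family size `k`) so a family can never contribute more effective
#' codons than it has members. Class means over the 2-, 3-, 4- and 6-fold
#' families give `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, capped at 61. A
#' missing 3-fold mean is imputed as `(F2 + F4) / 2`; if the 2-, 4- or
#' 6-fold class has no usable family the estimate is undefined and `NA` is
#' returned with a warning.
#'
#' @param counts A `codon_counts` vector, a `coding_sequence`, or any named
#'   numeric vector of sense-codon counts.
#' @return ENC in `[20, 61]`, or `NA` when undefined.
#' @export
#' @examples
#' cds <- validate_cds("x", "ATGAAAAAATAA")
#' # too few families for a defined ENC on a toy sequence:
#' # enc_observed() is meant for full-length CDS
enc_observed <- function(counts) {
  counts <- as_codon_counts(counts)
  fam_F <- numeric(0)
  fam_k <- integer(0)
  for (aa in AMINO_ACIDS) {
    fam <- SYN_FAMILIES[[aa]]
    k <- length(fam)
    if (k < 2L) next
    Fhat <- family_homozygosity(counts, fam)
    if (is.na(Fhat) || Fhat <= 0) next
    fam_F <- c(fam_F, max(Fhat, 1 / k))
    fam_k <- c(fam_k, k)
  }
  if (length(fam_F) == 0L) {
    stop("ENC undefined: no synonymous family with at least 2 codons")
  }
  cls_mean <- function(k) {
    if (any(fam_k == k)) mean(fam_F[fam_k == k]) else NA_real_
  }
  F2 <- cls_mean(2L)
  F3 <- cls_mean(3L)
  F4 <- cls_mean(4L)
  F6 <- cls_mean(6L)
  if (is.na(F3) && !is.na(F2) && !is.na(F4)) F3 <- (F2 + F4) / 2
  if (anyNA(c(F2, F3, F4, F6))) {
    warning("ENC undefined: a degeneracy class has no usable family")
    return(NA_real_)
  }
  min(2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6, 61)
}

#' Expected ENC under GC3 composition alone
#'
#' Wright's null expectation for a gene whose codon usage is shaped only
#' by its third-position G+C content `s`:
#' `ENC_expected = 2 + s + 29 / (s^2 + (1 - s)^2)`.
#'
#' @param s GC3 fraction(s) in `[0, 1]`; vectorised.
#' @return Expected ENC value(s).
#' @export
#' @examples
#' enc_expected(0.5)  # 60.5
enc_expected <- function(s) {
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
    stop("s must be in [0, 1]")
  }
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' ENC ratio
#'
#' The relative deviation `(ENC_expected - ENC_observed) / ENC_expected`,
#' negative when a gene uses more codons than its GC3 predicts.
#'
#' @param enc_obs Observed ENC.
#' @param enc_exp Expected ENC (> 0).
#' @return The ratio; vectorised.
#' @export
enc_ratio <- function(enc_obs, enc_exp) {
  if (any(enc_exp == 0)) stop("enc_exp must be non-zero")
  (enc_exp - enc_obs) / enc_exp
}

#' Relative synonymous codon usage
#'
#' For codon `j` of a synonymous family of size `k` with family total `n`,
#' `RSCU = x_j / (n / k)`: the observed count over the count expected under
#' uniform synonymous usage. ATG, TGG and the stop codons are excluded.
#' Unobserved families yield 0 for all members. Codons are classified as
#' `over_represented` (RSCU > 1.6), `preferred` (1 < RSCU <= 1.6),
#' `unbiased` (RSCU == 1) or `rare` (RSCU < 1).
#'
#' @param counts A `codon_counts` vector, `coding_sequence`, or named
#'   numeric vector of sense-codon counts.
#' @return An `rscu_table`: list with `rscu` (named numeric over the 59
#'   codons) and `class` (named character).
#' @export
#' @examples
#' r <- rscu(c(TTT = 3, TTC = 1))
#' r$rscu[c("TTT", "TTC")]  # 1.5, 0.5
rscu <- function(counts) {
  counts <- as_codon_counts(counts)
  vals <- stats::setNames(numeric(length(RSCU_CODONS)), RSCU_CODONS)
  for (aa in AMINO_ACIDS) {
    fam <- SYN_FAMILIES[[aa]]
    k <- length(fam)
    if (k < 2L) next
    n <- sum(counts[fam])
    vals[fam] <- if (n == 0) 0 else counts[fam] / (n / k)
  }
  cls <- ifelse(vals > 1.6, "over_represented",
                ifelse(vals > 1, "preferred",
                       ifelse(vals == 1, "unbiased", "rare")))
  structure(list(rscu = vals, class = stats::setNames(cls, RSCU_CODONS)),
            class = "rscu_table")
}

#' Sequences-by-codon RSCU matrix for a dataset
#'
#' @param dataset A `grouped_dataset`.
#' @return Numeric matrix, rows = sequences (named by id), columns = the 59
#'   synonymous codons.
#' @export
rscu_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "grouped_dataset"))
  rows <- vapply(dataset$sequences,
                 function(s) rscu(count_codons(s))$rscu,
                 numeric(length(RSCU_CODONS)))
  m <- t(rows)
  rownames(m) <- dataset_ids(dataset)
  m
}

#' Per-sequence ENC/RSCU summary table
#'
#' @param dataset A `grouped_dataset`.
#' @return A `data.frame` with `seq_id`, `group`, `gc3`, `enc_obs`,
#'   `enc_exp`, `enc_ratio` per accepted sequence.
#' @export
cub_table <- function(dataset) {
  stopifnot(inherits(dataset, "grouped_dataset"))
  rows <- lapply(dataset$sequences, function(s) {
    prof <- composition_profile(s)
    obs <- enc_observed(count_codons(s))
    ex <- enc_expected(prof$gc3)
    data.frame(seq_id = s$seq_id, group = s$group, gc3 = prof$gc3,
               enc_obs = obs, enc_exp = ex,
               enc_ratio = enc_ratio(obs, ex),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
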