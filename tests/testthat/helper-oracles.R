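# Independent oracles, written as plain step-by-step code so they share no
# internals with the implementation they check.

# Wright's ENC recomputed literally: per-family homozygosity, class means,
# 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, with the same flooring/capping
# conventions the package documents.
oracle_enc <- function(counts) {
  fams <- synonymous_families()
  F_by_class <- list()
  for (aa in names(fams)) {
    fam <- fams[[aa]]
    k <- length(fam)
    if (k < 2) next
    x <- counts[fam]
    x[is.na(x)] <- 0
    n <- sum(x)
    if (n < 2) next
    S <- 0
    for (codon in fam) S <- S + (x[[codon]] / n)^2
    Fh <- (n * S - 1) / (n - 1)
    if (Fh <= 0) next
    if (Fh < 1 / k) Fh <- 1 / k
    key <- as.character(k)
    F_by_class[[key]] <- c(F_by_class[[key]], Fh)
  }
  m <- function(key) if (is.null(F_by_class[[key]])) NA_real_ else mean(F_by_class[[key]])
  F2 <- m("2"); F3 <- m("3"); F4 <- m("4"); F6 <- m("6")
  if (is.na(F3) && !is.na(F2) && !is.na(F4)) F3 <- (F2 + F4) / 2
  if (anyNA(c(F2, F3, F4, F6))) return(NA_real_)
  min(2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6, 61)
}

# classical no-tie Spearman formula: 1 - 6 * sum(d^2) / (n (n^2 - 1))
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# total CA inertia from an independent chi-square computation
oracle_inertia <- function(mat) {
  unname(suppressWarnings(stats::chisq.test(mat)$statistic) / sum(mat))
}
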