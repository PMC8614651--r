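# Overall and position-specific nucleotide composition.

#' Nucleotide composition profile of a coding sequence
#'
#' All fractions are computed over the sense codons only (the terminal stop
#' codon is excluded, the initial ATG is included), so the composition
#' universe matches the one used for ENC and RSCU. `p1`, `p2`, `p3` are the
#' G+C fractions at codon positions 1, 2 and 3 (GC1/GC2/GC3); `p12` is
#' their first/second-position average, the response variable of the
#' neutrality plot. `a3`..`c3` are the single-base fractions at position 3
#' used by the parity-rule-2 plot. Values are stored as fractions in
#' `[0, 1]`; report writers rescale to percent.
#'
#' @param cds A `coding_sequence` (see [validate_cds()]).
#' @return A `composition_profile`: named list with `seq_id`, `group`,
#'   `length_nt`, `n_sense`, `a_pct`, `t_pct`, `g_pct`, `c_pct`, `gc_pct`,
#'   `p1`, `p2`, `p3`, `p12`, `a3`, `t3`, `g3`, `c3`, `gc3`.
#' @export
#' @examples
#' cds <- validate_cds("x", "ATGGGGCCCTAA")
#' composition_profile(cds)$gc_pct  # 7/9
composition_profile <- function(cds) {
  stopifnot(inherits(cds, "coding_sequence"))
  sense <- sense_of(cds)
  if (length(sense) == 0L) stop("no sense codons in ", cds$seq_id)
  b1 <- substr(sense, 1L, 1L)
  b2 <- substr(sense, 2L, 2L)
  b3 <- substr(sense, 3L, 3L)
  all_b <- c(b1, b2, b3)
  gc <- c("G", "C")
  p1 <- mean(b1 %in% gc)
  p2 <- mean(b2 %in% gc)
  p3 <- mean(b3 %in% gc)
  structure(list(
    seq_id = cds$seq_id, group = cds$group,
    length_nt = cds$length_nt, n_sense = length(sense),
    a_pct = mean(all_b == "A"), t_pct = mean(all_b == "T"),
    g_pct = mean(all_b == "G"), c_pct = mean(all_b == "C"),
    gc_pct = mean(all_b %in% gc),
    p1 = p1, p2 = p2, p3 = p3, p12 = (p1 + p2) / 2,
    a3 = mean(b3 == "A"), t3 = mean(b3 == "T"),
    g3 = mean(b3 == "G"), c3 = mean(b3 == "C"),
    gc3 = mean(b3 %in% gc)), class = "composition_profile")
}

#' Third-position base fractions, optionally restricted to fourfold families
#'
#' Used by the parity-rule-2 analysis. With `fourfold_only = TRUE` only
#' codons belonging to fourfold-degenerate families (Ala, Gly, Pro, Thr,
#' Val) contribute, the classical PR2 restriction in which position 3 is
#' free of amino-acid constraint.
#'
#' @param cds A `coding_sequence`.
#' @param fourfold_only Restrict to fourfold-degenerate families?
#' @return Named list `a3`, `t3`, `g3`, `c3` (fractions, or `NaN` when no
#'   codon qualifies).
#' @export
third_position_fractions <- function(cds, fourfold_only = FALSE) {
  sense <- sense_of(cds)
  if (fourfold_only) {
    four <- unlist(SYN_FAMILIES[lengths(SYN_FAMILIES) == 4L], use.names = FALSE)
    sense <- sense[sense %in% four]
  }
  b3 <- substr(sense, 3L, 3L)
  list(a3 = mean(b3 == "A"), t3 = mean(b3 == "T"),
       g3 = mean(b3 == "G"), c3 = mean(b3 == "C"))
}

#' Per-sequence composition table for a dataset
#'
#' @param dataset A `grouped_dataset`.
#' @return A `data.frame` with one row per accepted sequence and the fields
#'   of [composition_profile()].
#' @export
composition_table <- function(dataset) {
  stopifnot(inherits(dataset, "grouped_dataset"))
  rows <- lapply(dataset$sequences, function(s) {
    as.data.frame(unclass(composition_profile(s)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# metrics stored as fractions but reported on the percent scale
PCT_METRICS <- c("a_pct", "t_pct", "g_pct", "c_pct", "gc_pct",
                 "p1", "p2", "p3", "p12", "a3", "t3", "g3", "c3", "gc3")

#' Group-level mean and standard deviation of per-sequence metrics
#'
#' Computes, per group, the mean and sample standard deviation (n - 1
#' denominator; reported as 0 when n = 1) of every numeric metric column.
#' Fraction-scale composition metrics are rescaled to percent so the
#' summary matches the conventional mean +/- SD presentation of
#' codon-usage tables.
#'
#' @param metrics A `data.frame` of per-sequence values containing a group
#'   column plus numeric metric columns (e.g. the output of
#'   [composition_table()] merged with ENC and protein properties).
#' @param group_col Name of the group column (default `"group"`).
#' @return A `data.frame` with one row per group: `group`, `n`, then
#'   `<metric>_mean` and `<metric>_sd` for every metric column.
#' @export
summarize_groups <- function(metrics, group_col = "group") {
  stopifnot(is.data.frame(metrics), group_col %in% names(metrics),
            nrow(metrics) >= 1L)
  num_cols <- names(metrics)[vapply(metrics, is.numeric, TRUE)]
  out <- lapply(split(metrics, metrics[[group_col]]), function(df) {
    row <- data.frame(group = df[[group_col]][1L], n = nrow(df),
                      stringsAsFactors = FALSE)
    for (m in num_cols) {
      x <- df[[m]]
      if (m %in% PCT_METRICS) x <- 100 * x
      row[[paste0(m, "_mean")]] <- mean(x, na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- if (sum(!is.na(x)) >= 2L) {
        stats::sd(x, na.rm = TRUE)
      } else 0
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
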