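# Translation and protein-level properties: amino-acid usage, GRAVY
# (mean Kyte-Doolittle hydropathy) and aromaticity (relative frequency of
# Phe + Tyr + Trp).

#' Translate a coding sequence
#'
#' Maps the sense codons through the standard genetic code; the terminal
#' stop codon is dropped. Validation upstream guarantees no internal
#' stops.
#'
#' @param cds A `coding_sequence`.
#' @return One-letter amino-acid string, one residue per sense codon.
#' @export
#' @examples
#' translate_cds(validate_cds("x", "ATGAAATAA"))  # "MK"
translate_cds <- function(cds) {
  stopifnot(inherits(cds, "coding_sequence"))
  paste(GENCODE[sense_of(cds)], collapse = "")
}

#' Amino-acid usage, GRAVY and aromaticity of a protein
#'
#' @param protein Non-empty one-letter amino-acid string (standard 20
#'   residues only).
#' @return A `protein_profile`: list with `aa_freq` (named frequencies
#'   over the 20 amino acids, summing to 1), `gravy` (mean Kyte-Doolittle
#'   hydropathy; negative values indicate a hydrophilic, soluble protein),
#'   `aromaticity` (frequency of F + Y + W) and `n_residues`.
#' @export
#' @examples
#' protein_profile("FYWAAAAAAA")$aromaticity  # 0.3
protein_profile <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (!nzchar(protein)) stop("empty protein")
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(aa), AMINO_ACIDS)
  if (length(bad) > 0L) {
    stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  }
  freq <- as.numeric(table(factor(aa, levels = AMINO_ACIDS))) / length(aa)
  freq <- stats::setNames(freq, AMINO_ACIDS)
  structure(list(aa_freq = freq,
                 gravy = mean(KD_HYDROPATHY[aa]),
                 aromaticity = sum(freq[AROMATIC_AA]),
                 n_residues = length(aa)),
            class = "protein_profile")
}

#' Per-sequence protein property table for a dataset
#'
#' @param dataset A `grouped_dataset`.
#' @return A `data.frame` with `seq_id`, `group`, `gravy`, `aromaticity`
#'   and one `freq_<aa>` column per amino acid.
#' @export
protein_table <- function(dataset) {
  stopifnot(inherits(dataset, "grouped_dataset"))
  rows <- lapply(dataset$sequences, function(s) {
    pp <- protein_profile(translate_cds(s))
    row <- data.frame(seq_id = s$seq_id, group = s$group,
                      gravy = pp$gravy, aromaticity = pp$aromaticity,
                      stringsAsFactors = FALSE)
    for (a in AMINO_ACIDS) row[[paste0("freq_", a)]] <- pp$aa_freq[[a]]
    row
  })
  do.call(rbind, rows)
}
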