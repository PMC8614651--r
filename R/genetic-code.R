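# Shared genetic-code tables, built once at install time from the standard
# code shipped with Biostrings. All downstream modules index into these.

GENCODE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

STOP_CODONS  <- names(GENCODE)[GENCODE == "*"]
SENSE_CODONS <- names(GENCODE)[GENCODE != "*"]

# synonymous families keyed by one-letter amino acid (20 entries, sizes 1-6)
SYN_FAMILIES <- split(SENSE_CODONS, GENCODE[SENSE_CODONS])

# the 59 codons with a synonymous alternative (61 sense codons minus the
# non-degenerate ATG and TGG)
RSCU_CODONS <- setdiff(SENSE_CODONS, c("ATG", "TGG"))

AMINO_ACIDS <- names(SYN_FAMILIES)

# Kyte-Doolittle (1982) hydropathy scale; GRAVY is its per-residue mean
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

AROMATIC_AA <- c("F", "Y", "W")

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 sense codons (DNA alphabet).
#' @export
#' @examples
#' length(sense_codons())
sense_codons <- function() SENSE_CODONS

#' The 59 codons subject to synonymous choice
#'
#' The sense codons excluding ATG (Met) and TGG (Trp), which have no
#' synonymous alternative and therefore carry no usage-bias signal.
#'
#' @return Character vector of 59 codons.
#' @export
rscu_codons <- function() RSCU_CODONS

#' Synonymous codon families of the standard genetic code
#'
#' @return Named list with one character vector of codons per amino acid
#'   (one-letter code); family sizes are 1, 2, 3, 4 or 6.
#' @export
#' @examples
#' synonymous_families()[["L"]]  # the six leucine codons
synonymous_families <- function() SYN_FAMILIES
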