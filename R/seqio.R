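# Reading, validating and codon-tokenising coding sequences.

#' Read a FASTA file of coding sequences
#'
#' Reads plain or gzip-compressed FASTA. Headers are split at the first
#' whitespace to form the sequence id; sequences are uppercased and RNA
#' uracil is normalised to thymine. No validation beyond parsing is done
#' here — see [validate_cds()].
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `seq_id` and `sequence`, one row per
#'   record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop("failed to read FASTA '", path, "': ",
                         conditionMessage(e))
                  })
  if (length(set) == 0L) {
    warning("no sequences found in ", path)
    return(data.frame(seq_id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(chartr("Uu", "Tt", as.character(set)))
  data.frame(seq_id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

new_coding_sequence <- function(seq_id, group, sequence) {
  n <- nchar(sequence)
  codons <- substring(sequence, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  structure(list(seq_id = seq_id, group = group, sequence = sequence,
                 codons = codons, length_nt = n),
            class = "coding_sequence")
}

#' Validate a raw sequence as a coding sequence
#'
#' A valid CDS contains only A/C/G/T, has a length that is a multiple of
#' three, starts with ATG, ends with a stop codon (TAA/TAG/TGA) and has no
#' internal stop codon. Checks are applied in that fixed order and the
#' first failure names the rejection, so rejection reasons are
#' reproducible. Rejections are returned as data, not raised as errors.
#'
#' @param seq_id Sequence identifier.
#' @param raw Non-empty DNA string (already uppercased, T not U).
#' @param group Group label to attach (default `"all"`).
#' @return A `coding_sequence` object, or a `cds_rejection` object with
#'   fields `seq_id` and `reason` (one of `ambiguous_base`,
#'   `not_multiple_of_3`, `bad_start`, `bad_stop`, `internal_stop`).
#' @export
#' @examples
#' validate_cds("s1", "ATGAAATAA")
#' validate_cds("s2", "ATGAANTAA")$reason
validate_cds <- function(seq_id, raw, group = "all") {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  reject <- function(reason) {
    structure(list(seq_id = seq_id, reason = reason), class = "cds_rejection")
  }
  if (grepl("[^ACGT]", raw)) return(reject("ambiguous_base"))
  if (nchar(raw) %% 3L != 0L) return(reject("not_multiple_of_3"))
  cds <- new_coding_sequence(seq_id, group, raw)
  k <- length(cds$codons)
  if (cds$codons[1L] != "ATG") return(reject("bad_start"))
  if (!(cds$codons[k] %in% STOP_CODONS)) return(reject("bad_stop"))
  if (k > 2L && any(cds$codons[-k] %in% STOP_CODONS)) {
    return(reject("internal_stop"))
  }
  cds
}

# sense codons of a CDS: everything but the terminal stop. The initial ATG
# is a real Met codon and is retained; all downstream counting uses this.
sense_of <- function(cds) utils::head(cds$codons, -1L)

read_group_table <- function(path) {
  if (!file.exists(path)) stop("group table not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("group table must have two columns (seq_id, group)")
  tab <- tab[, 1:2]
  names(tab) <- c("seq_id", "group")
  if (nrow(tab) > 0L &&
      identical(tolower(trimws(unlist(tab[1L, ]))), c("seq_id", "group"))) {
    tab <- tab[-1L, , drop = FALSE]  # optional header row
  }
  stats::setNames(tab$group, tab$seq_id)
}

new_grouped_dataset <- function(sequences, rejected) {
  groups <- sort(unique(vapply(sequences, `[[`, "", "group")))
  if (is.null(rejected) || length(rejected) == 0L) {
    rejected <- data.frame(seq_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  }
  structure(list(sequences = sequences, groups = groups, rejected = rejected),
            class = "grouped_dataset")
}

#' Load and validate a grouped CDS dataset
#'
#' Reads a FASTA file and a two-column TSV (`seq_id`, `group`; header row
#' optional), validates every record with [validate_cds()], and partitions
#' the results into accepted sequences and a rejection log. Every FASTA id
#' must be present in the group table.
#'
#' @param fasta Path to the FASTA file.
#' @param group_table Path to the TSV mapping sequence ids to group labels.
#' @return A `grouped_dataset`: list with `sequences` (list of
#'   `coding_sequence`), `groups` (sorted unique labels of the accepted
#'   sequences) and `rejected` (data.frame of `seq_id`, `reason`).
#' @export
load_dataset <- function(fasta, group_table) {
  recs <- read_fasta(fasta)
  if (nrow(recs) == 0L) stop("no sequences in FASTA: ", fasta)
  map <- read_group_table(group_table)
  missing <- setdiff(recs$seq_id, names(map))
  if (length(missing) > 0L) {
    stop("sequence id(s) missing from group table: ",
         paste(missing, collapse = ", "))
  }
  seqs <- list()
  rej <- list()
  for (i in seq_len(nrow(recs))) {
    id <- recs$seq_id[i]
    res <- validate_cds(id, recs$sequence[i], unname(map[[id]]))
    if (inherits(res, "cds_rejection")) {
      rej[[length(rej) + 1L]] <- data.frame(seq_id = res$seq_id,
                                            reason = res$reason,
                                            stringsAsFactors = FALSE)
    } else {
      seqs[[length(seqs) + 1L]] <- res
    }
  }
  new_grouped_dataset(seqs, do.call(rbind, rej))
}

#' Write the accepted sequences of a dataset to FASTA
#'
#' @param x A `grouped_dataset` or a named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "grouped_dataset")) {
    seqs <- vapply(x$sequences, `[[`, "", "sequence")
    names(seqs) <- vapply(x$sequences, `[[`, "", "seq_id")
  } else {
    seqs <- x
    if (is.null(names(seqs))) stop("sequences must be named")
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("<coding_sequence> ", x$seq_id, " [", x$group, "]: ",
      x$length_nt, " nt, ", length(x$codons) - 1L, " sense codons\n", sep = "")
  invisible(x)
}

#' @export
print.grouped_dataset <- function(x, ...) {
  cat("<grouped_dataset> ", length(x$sequences), " sequences in ",
      length(x$groups), " group(s); ", nrow(x$rejected), " rejected\n",
      sep = "")
  for (g in x$groups) {
    n <- sum(vapply(x$sequences, `[[`, "", "group") == g)
    cat("  ", g, ": ", n, "\n", sep = "")
  }
  invisible(x)
}

# per-sequence group labels, in dataset order
dataset_groups <- function(dataset) {
  vapply(dataset$sequences, `[[`, "", "group")
}

dataset_ids <- function(dataset) {
  vapply(dataset$sequences, `[[`, "", "seq_id")
}
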