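# Fixtures are built in code at test time; no data files.

make_cds <- function(seq, id = "s1", group = "all") {
  res <- validate_cds(id, seq, group)
  if (inherits(res, "cds_rejection")) {
    stop("fixture is not a valid CDS: ", res$reason)
  }
  res
}

# write a FASTA file from named sequences, return its path
tmp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

# write a two-column group table, return its path
tmp_groups <- function(ids, groups, header = FALSE) {
  path <- tempfile(fileext = ".tsv")
  lines <- paste(ids, groups, sep = "\t")
  if (header) lines <- c("seq_id\tgroup", lines)
  writeLines(lines, path)
  path
}

# random sense-codon count table (named vector over the 61 codons)
random_count_table <- function(lambda = 5) {
  stats::setNames(stats::rpois(61, lambda), sense_codons())
}

# dataset written to disk: list(fasta=, groups=)
panel_files <- function(panel) {
  ids <- vapply(panel$sequences, `[[`, "", "seq_id")
  gl <- vapply(panel$sequences, `[[`, "", "group")
  fa <- tempfile(fileext = ".fasta")
  write_fasta(panel, fa)
  list(fasta = fa, groups = tmp_groups(ids, gl))
}
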