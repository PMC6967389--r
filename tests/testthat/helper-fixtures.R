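# Shared fixtures: deterministic random coding sequences and small genomes
# built in code.

fixture_cds <- function(n_codons, seed) {
  withr::with_seed(seed, {
    paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
  })
}

fixture_genome <- function(id, nt_seqs, gene_ids = NULL) {
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("g%03d", seq_along(nt_seqs))
  }
  genome(id, data.frame(gene_id = gene_ids, nt_seq = nt_seqs,
                        stringsAsFactors = FALSE))
}

fixture_fasta <- function(ids, seqs) {
  path <- tempfile(fileext = ".fna")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

hamming_identity <- function(genome_a, genome_b) {
  stopifnot(identical(genome_a$genes$gene_id, genome_b$genes$gene_id))
  diffs <- mapply(function(x, y) {
    sum(strsplit(x, "")[[1L]] != strsplit(y, "")[[1L]])
  }, genome_a$genes$nt_seq, genome_b$genes$nt_seq)
  1 - sum(diffs) / genome_a$total_gene_length
}
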