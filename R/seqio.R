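# Sequence and table IO: gene FASTA in/out, coding-sequence validation and
# the per-pair summary table writer.

#' Construct a genome object
#'
#' A genome is a collection of validated coding sequences (genes). Gene ids
#' must be unique within the genome.
#'
#' @param genome_id Single string identifying the genome.
#' @param genes `data.frame` with columns `gene_id`, `nt_seq` and optionally
#'   `aa_seq` (derived by translation when absent).
#' @return An object of class `genome` with elements `genome_id`, `genes`
#'   (with `gene_id`, `nt_seq`, `aa_seq`, `length`) and `total_gene_length`.
#' @export
genome <- function(genome_id, genes) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L,
            is.data.frame(genes), all(c("gene_id", "nt_seq") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) {
    stop("gene ids must be unique within a genome")
  }
  if (is.null(genes$aa_seq)) {
    genes$aa_seq <- vapply(genes$nt_seq, translate_cds, character(1L),
                           USE.NAMES = FALSE)
  }
  genes$length <- nchar(genes$nt_seq)
  rownames(genes) <- NULL
  structure(
    list(genome_id = genome_id,
         genes = genes[, c("gene_id", "nt_seq", "aa_seq", "length")],
         total_gene_length = sum(genes$length)),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d genes, %d nt total\n",
              x$genome_id, nrow(x$genes), x$total_gene_length))
  invisible(x)
}

n_genes <- function(g) nrow(g$genes)

#' Read a gene FASTA file into a genome
#'
#' Each FASTA record is one coding sequence; the first whitespace-delimited
#' header token is taken as the gene id. Records failing coding-sequence
#' validation (frame, alphabet, internal stops, minimum length) are dropped
#' with a warning giving the count. If a matching protein FASTA is supplied,
#' records whose provided translation disagrees with the standard-code
#' translation are also dropped.
#'
#' @param path Path to a nucleotide FASTA file.
#' @param genome_id Genome identifier; defaults to the file name stem.
#' @param min_length Minimum gene length in nt (default 60); shorter genes
#'   are dropped.
#' @param protein_path Optional protein FASTA with matching gene ids,
#'   checked against the translation.
#' @return A [genome()] object.
#' @export
read_gene_fasta <- function(path, genome_id = NULL, min_length = 60L,
                            protein_path = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read FASTA file: %s", path))
  }
  if (is.null(genome_id)) {
    genome_id <- tools::file_path_sans_ext(basename(path))
  }
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  nt <- toupper(as.character(seqs))

  dup <- duplicated(ids)
  if (any(dup)) {
    warning(sprintf("%s: dropped %d records with duplicate gene ids",
                    genome_id, sum(dup)))
    ids <- ids[!dup]
    nt <- nt[!dup]
  }

  reasons <- vapply(nt, function(s) {
    r <- validate_cds(s, min_length = min_length)
    if (is.null(r)) "" else r
  }, character(1L), USE.NAMES = FALSE)
  bad <- reasons != ""
  if (any(bad)) {
    warning(sprintf("%s: dropped %d of %d records failing CDS validation (%s)",
                    genome_id, sum(bad), length(bad),
                    paste(unique(reasons[bad]), collapse = "; ")))
    ids <- ids[!bad]
    nt <- nt[!bad]
  }
  if (length(nt) == 0L) {
    stop(sprintf("%s: no valid coding sequences in %s", genome_id, path))
  }

  aa <- vapply(nt, translate_cds, character(1L), USE.NAMES = FALSE)

  if (!is.null(protein_path)) {
    prot <- Biostrings::readAAStringSet(protein_path)
    pid <- sub("\\s.*$", "", names(prot))
    paa <- sub("\\*$", "", toupper(as.character(prot)))
    idx <- match(ids, pid)
    mismatch <- !is.na(idx) & paa[idx] != aa
    if (any(mismatch)) {
      warning(sprintf(
        "%s: dropped %d records whose protein FASTA disagrees with translation",
        genome_id, sum(mismatch)))
      keep <- !mismatch
      ids <- ids[keep]; nt <- nt[keep]; aa <- aa[keep]
    }
    if (length(nt) == 0L) {
      stop(sprintf("%s: no records left after protein cross-check", genome_id))
    }
  }

  genome(genome_id,
         data.frame(gene_id = ids, nt_seq = nt, aa_seq = aa,
                    stringsAsFactors = FALSE))
}

#' Write a genome's genes to a FASTA file
#'
#' @param g A [genome()] object.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_gene_fasta <- function(g, path) {
  stopifnot(inherits(g, "genome"))
  x <- Biostrings::DNAStringSet(g$genes$nt_seq)
  names(x) <- g$genes$gene_id
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Write per-pair metrics to a tab-separated table
#'
#' One row per unordered genome pair; a pair present in both orientations is
#' an error. Floating-point columns are written at 6 decimals, with `.` as
#' the decimal mark.
#'
#' @param results `data.frame` of per-pair rows; must contain `genome1` and
#'   `genome2` columns.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_pair_table <- function(results, path) {
  stopifnot(is.data.frame(results),
            all(c("genome1", "genome2") %in% names(results)))
  if (nrow(results) > 0L) {
    key <- paste(pmin(results$genome1, results$genome2),
                 pmax(results$genome1, results$genome2), sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate unordered genome pair in results")
    }
  }
  out <- results
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "NA", sprintf("%.6f", out[[j]]))
    }
  }
  write.table(out, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
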