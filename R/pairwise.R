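# Gene-by-gene genome comparison: k-mer candidate prescreen, reciprocal
# best hits under identity/coverage filters, codon alignments, and
# genome-wide ANI / alignment fraction.

#' K-mer prescreen for candidate ortholog pairs
#'
#' Returns exactly the gene pairs sharing at least `min_shared` distinct
#' k-mers. With the defaults (k = 11, min_shared = 3) true ortholog pairs at
#' moderate divergence share many k-mers while unrelated random genes are
#' essentially never retained.
#'
#' @param genes_a,genes_b [genome()] objects or data frames with `gene_id`
#'   and `nt_seq` columns.
#' @param k K-mer length, between 8 and 16.
#' @param min_shared Minimum number of distinct shared k-mers.
#' @return `data.frame` with `gene_a`, `gene_b`, `shared_kmers`.
#' @export
kmer_prescreen <- function(genes_a, genes_b, k = 11L, min_shared = 3L) {
  if (k < 8L || k > 16L) {
    stop("k must be between 8 and 16")
  }
  ga <- if (inherits(genes_a, "genome")) genes_a$genes else genes_a
  gb <- if (inherits(genes_b, "genome")) genes_b$genes else genes_b

  kmer_codes <- function(seqs) {
    lapply(seqs, function(s) {
      b <- match(strsplit(s, "", fixed = TRUE)[[1L]], DNA_BASES) - 1L
      n <- length(b)
      if (n < k) return(numeric(0L))
      # rolling base-4 code as a double (exact for k <= 16 < 2^53)
      code <- numeric(n - k + 1L)
      for (j in seq_len(k)) {
        code <- code * 4 + b[j:(n - k + j)]
      }
      unique(code)
    })
  }

  ka <- kmer_codes(ga$nt_seq)
  kb <- kmer_codes(gb$nt_seq)
  dta <- data.table::data.table(
    kmer = unlist(ka, use.names = FALSE),
    ia = rep.int(seq_along(ka), lengths(ka)))
  dtb <- data.table::data.table(
    kmer = unlist(kb, use.names = FALSE),
    ib = rep.int(seq_along(kb), lengths(kb)))
  if (nrow(dta) == 0L || nrow(dtb) == 0L) {
    return(data.frame(gene_a = character(0L), gene_b = character(0L),
                      shared_kmers = integer(0L)))
  }
  joined <- merge(dta, dtb, by = "kmer", allow.cartesian = TRUE)
  if (nrow(joined) == 0L) {
    return(data.frame(gene_a = character(0L), gene_b = character(0L),
                      shared_kmers = integer(0L)))
  }
  ia <- ib <- NULL  # appease R CMD check; data.table NSE
  counts <- joined[, list(shared_kmers = .N), by = list(ia, ib)]
  counts <- counts[counts$shared_kmers >= min_shared, ]
  out <- data.frame(gene_a = ga$gene_id[counts$ia],
                    gene_b = gb$gene_id[counts$ib],
                    shared_kmers = counts$shared_kmers)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Reciprocal best hits with identity and coverage filters
#'
#' A pair (a, b) is a reciprocal best hit when b is a's highest-scoring
#' partner and a is b's (ties broken deterministically by lexicographic
#' gene id). Retained RBH pairs must reach `min_identity` nucleotide
#' identity and cover at least `min_coverage` of the shorter gene.
#'
#' @param scored `data.frame` of scored candidate pairs with columns
#'   `gene_a`, `gene_b`, `score`, `identity`, `coverage_shorter`.
#' @param min_identity Minimum nucleotide identity (default 0.70).
#' @param min_coverage Minimum coverage of the shorter gene (default 0.70).
#' @return Subset of `scored` rows that are retained RBH pairs.
#' @export
reciprocal_best_hits <- function(scored, min_identity = 0.70,
                                 min_coverage = 0.70) {
  stopifnot(all(c("gene_a", "gene_b", "score", "identity",
                  "coverage_shorter") %in% names(scored)))
  if (nrow(scored) == 0L) {
    return(scored)
  }
  keep <- scored[mutual_best(scored$gene_a, scored$gene_b, scored$score), ,
                 drop = FALSE]
  keep <- keep[keep$identity >= min_identity &
                 keep$coverage_shorter >= min_coverage, , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

# logical index of rows that are mutual best hits by score, with ties
# broken in favour of the lexicographically smallest partner id
mutual_best <- function(gene_a, gene_b, score) {
  n <- length(score)
  ord_a <- order(-score, gene_b)
  best_for_a <- ord_a[!duplicated(gene_a[ord_a])]
  ord_b <- order(-score, gene_a)
  best_for_b <- ord_b[!duplicated(gene_b[ord_b])]
  key <- paste(gene_a, gene_b, sep = "\r")
  key %in% intersect(key[best_for_a], key[best_for_b])
}

#' Codon alignment from a protein alignment and the source CDSs
#'
#' Maps each aligned residue pair back to its source codons. Columns where
#' either side is a gap are excluded, so the output codon columns are
#' gap-free and their count equals the number of gap-free aligned residue
#' pairs. The protein alignment must be consistent with the translations of
#' the two coding sequences.
#'
#' @param protein_alignment Result of [global_protein_align()].
#' @param nt_a,nt_b The two coding sequences.
#' @return List with `codons_a`, `codons_b` (equal-length codon vectors).
#' @export
codon_alignment <- function(protein_alignment, nt_a, nt_b) {
  ca <- strsplit(protein_alignment$aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(protein_alignment$aligned_b, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  if (paste(ca[ca != "-"], collapse = "") != translate_cds(nt_a) ||
      paste(cb[cb != "-"], collapse = "") != translate_cds(nt_b)) {
    stop("protein alignment is inconsistent with the coding sequences")
  }
  pos_a <- cumsum(ca != "-")
  pos_b <- cumsum(cb != "-")
  keep <- ca != "-" & cb != "-"
  cods_a <- split_codons(nt_a)
  cods_b <- split_codons(nt_b)
  list(codons_a = cods_a[pos_a[keep]], codons_b = cods_b[pos_b[keep]])
}

#' Compare two genomes gene by gene
#'
#' Runs the k-mer prescreen, scores candidate pairs by optimal global
#' nucleotide alignment, keeps reciprocal best hits passing the 70%/70%
#' identity/coverage filter, and (optionally) builds codon alignments from
#' BLOSUM62 protein alignments of each retained pair. Genome-wide ANI is
#' the length-weighted mean of per-gene identities; the alignment fraction
#' is the aligned share of total gene length, averaged over the two
#' genomes. The computation is symmetric: genomes are ordered internally by
#' genome id, so `compare_genomes(A, B)` and `compare_genomes(B, A)` return
#' identical results.
#'
#' @param genome_a,genome_b [genome()] objects.
#' @param k,min_shared Prescreen parameters (see [kmer_prescreen()]).
#' @param min_identity,min_coverage RBH filters (see
#'   [reciprocal_best_hits()]).
#' @param codon Build codon alignments for each RBH pair (default `TRUE`;
#'   required for [pair_dnds()], not needed for
#'   [enriched_identical_genes()]).
#' @return An object of class `genome_pair_result`: list with `genome_a`,
#'   `genome_b`, `alignments` (per-gene table), `codon_alignments`, `ani`
#'   (fraction), `alignment_fraction`, `n_genes_aligned`, `no_alignment`.
#'   With zero retained RBH pairs the result is flagged `no_alignment` and
#'   `ani` is `NA`, not 0.
#' @export
compare_genomes <- function(genome_a, genome_b, k = 11L, min_shared = 3L,
                            min_identity = 0.70, min_coverage = 0.70,
                            codon = TRUE) {
  stopifnot(inherits(genome_a, "genome"), inherits(genome_b, "genome"))
  if (n_genes(genome_a) == 0L || n_genes(genome_b) == 0L) {
    stop("both genomes must contain at least one gene")
  }
  if (genome_b$genome_id < genome_a$genome_id) {
    tmp <- genome_a; genome_a <- genome_b; genome_b <- tmp
  }

  no_alignment_result <- function() {
    structure(
      list(genome_a = genome_a$genome_id, genome_b = genome_b$genome_id,
           alignments = NULL, codon_alignments = NULL,
           ani = NA_real_, alignment_fraction = NA_real_,
           n_genes_aligned = 0L, no_alignment = TRUE),
      class = "genome_pair_result")
  }

  cand <- kmer_prescreen(genome_a, genome_b, k = k, min_shared = min_shared)
  if (nrow(cand) == 0L) {
    return(no_alignment_result())
  }

  ia <- match(cand$gene_a, genome_a$genes$gene_id)
  ib <- match(cand$gene_b, genome_b$genes$gene_id)
  n_cand <- nrow(cand)
  gp <- biostrings_gap(5, 2)

  # batch optimal-alignment scores, one call per subject gene, to keep the
  # per-call overhead off the (much larger) candidate list
  score <- numeric(n_cand)
  for (grp in split(seq_len(n_cand), ib)) {
    score[grp] <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(genome_a$genes$nt_seq[ia[grp]]),
      Biostrings::DNAString(genome_b$genes$nt_seq[ib[grp[1L]]]),
      substitutionMatrix = nt_submat(),
      gapOpening = gp[["opening"]], gapExtension = gp[["extension"]],
      type = "global", scoreOnly = TRUE)
  }

  # mutual best hits by score, then per-gene alignment stats for those only
  sel <- which(mutual_best(cand$gene_a, cand$gene_b, score))
  if (length(sel) == 0L) {
    return(no_alignment_result())
  }
  n_sel <- length(sel)
  identity <- cov_a <- cov_b <- numeric(n_sel)
  alen <- matches <- integer(n_sel)
  for (r in seq_len(n_sel)) {
    i <- sel[r]
    sa <- genome_a$genes$nt_seq[ia[i]]
    sb <- genome_b$genes$nt_seq[ib[i]]
    if (nchar(sa) == nchar(sb)) {
      va <- strsplit(sa, "", fixed = TRUE)[[1L]]
      vb <- strsplit(sb, "", fixed = TRUE)[[1L]]
      nmatch <- sum(va == vb)
      if (2 * nmatch - length(va) == score[i]) {
        # the gapless alignment is optimal: stats without traceback
        alen[r] <- length(va)
        matches[r] <- nmatch
        identity[r] <- nmatch / length(va)
        cov_a[r] <- 1
        cov_b[r] <- 1
        next
      }
    }
    al <- global_nt_align(sa, sb)
    identity[r] <- al$identity
    alen[r] <- al$aligned_length
    matches[r] <- al$matches
    cov_a[r] <- al$coverage_a
    cov_b[r] <- al$coverage_b
  }
  len_a <- genome_a$genes$length[ia[sel]]
  len_b <- genome_b$genes$length[ib[sel]]
  rbh <- data.frame(
    gene_a = cand$gene_a[sel], gene_b = cand$gene_b[sel],
    score = score[sel], identity = identity,
    aligned_length = alen, matches = matches,
    coverage_a = cov_a, coverage_b = cov_b,
    coverage_shorter = ifelse(len_a <= len_b, cov_a, cov_b),
    stringsAsFactors = FALSE)
  rbh <- rbh[rbh$identity >= min_identity &
               rbh$coverage_shorter >= min_coverage, , drop = FALSE]
  if (nrow(rbh) == 0L) {
    return(no_alignment_result())
  }
  rbh <- rbh[order(rbh$gene_a, rbh$gene_b), , drop = FALSE]
  rownames(rbh) <- NULL
  rbh$is_identical <- rbh$matches == rbh$aligned_length

  codon_alignments <- NULL
  if (codon) {
    ja <- match(rbh$gene_a, genome_a$genes$gene_id)
    jb <- match(rbh$gene_b, genome_b$genes$gene_id)
    codon_alignments <- vector("list", nrow(rbh))
    b62 <- blosum62()
    gpa <- biostrings_gap(12, 3)
    for (r in seq_len(nrow(rbh))) {
      aa_a <- genome_a$genes$aa_seq[ja[r]]
      aa_b <- genome_b$genes$aa_seq[jb[r]]
      nt_a <- genome_a$genes$nt_seq[ja[r]]
      nt_b <- genome_b$genes$nt_seq[jb[r]]
      done <- FALSE
      if (nchar(aa_a) == nchar(aa_b)) {
        ra <- strsplit(aa_a, "", fixed = TRUE)[[1L]]
        rb <- strsplit(aa_b, "", fixed = TRUE)[[1L]]
        gapless_score <- sum(b62[cbind(ra, rb)])
        dp_score <- Biostrings::pairwiseAlignment(
          aa_a, aa_b, substitutionMatrix = b62,
          gapOpening = gpa[["opening"]], gapExtension = gpa[["extension"]],
          type = "global", scoreOnly = TRUE)
        if (gapless_score == dp_score) {
          n_aa <- length(ra)
          codon_alignments[[r]] <- list(
            codons_a = split_codons(nt_a)[seq_len(n_aa)],
            codons_b = split_codons(nt_b)[seq_len(n_aa)])
          done <- TRUE
        }
      }
      if (!done) {
        pal <- global_protein_align(aa_a, aa_b)
        codon_alignments[[r]] <- codon_alignment(pal, nt_a, nt_b)
      }
    }
  }

  ja <- match(rbh$gene_a, genome_a$genes$gene_id)
  jb <- match(rbh$gene_b, genome_b$genes$gene_id)
  aligned_bases_a <- round(rbh$coverage_a * genome_a$genes$length[ja])
  aligned_bases_b <- round(rbh$coverage_b * genome_b$genes$length[jb])
  af <- mean(c(sum(aligned_bases_a) / genome_a$total_gene_length,
               sum(aligned_bases_b) / genome_b$total_gene_length))

  structure(
    list(genome_a = genome_a$genome_id, genome_b = genome_b$genome_id,
         alignments = rbh, codon_alignments = codon_alignments,
         ani = sum(rbh$identity * rbh$aligned_length) /
           sum(rbh$aligned_length),
         alignment_fraction = af,
         n_genes_aligned = nrow(rbh), no_alignment = FALSE),
    class = "genome_pair_result")
}

#' @export
print.genome_pair_result <- function(x, ...) {
  if (isTRUE(x$no_alignment)) {
    cat(sprintf("<genome_pair_result> %s vs %s: no alignment\n",
                x$genome_a, x$genome_b))
  } else {
    cat(sprintf(
      "<genome_pair_result> %s vs %s: %d RBH genes, ANI %.4f, af %.3f\n",
      x$genome_a, x$genome_b, x$n_genes_aligned, x$ani,
      x$alignment_fraction))
  }
  invisible(x)
}

#' Summarize a genome pair as one table row
#'
#' Collects the comparison, dN/dS and recombination results for one genome
#' pair into a single row suitable for [write_pair_table()] and the
#' population-level summaries. ANI is reported on the 0-100 percent scale
#' here (the `genome_pair_result` itself stores a fraction).
#'
#' @param pair_result A [compare_genomes()] result.
#' @param dnds Optional [pair_dnds()] result.
#' @param recomb Optional [enriched_identical_genes()] result.
#' @return One-row `data.frame`.
#' @export
summarize_pair <- function(pair_result, dnds = NULL, recomb = NULL) {
  stopifnot(inherits(pair_result, "genome_pair_result"))
  row <- data.frame(
    genome1 = pair_result$genome_a,
    genome2 = pair_result$genome_b,
    ani = if (isTRUE(pair_result$no_alignment)) NA_real_ else
      100 * pair_result$ani,
    alignment_fraction = pair_result$alignment_fraction,
    n_genes_aligned = pair_result$n_genes_aligned,
    no_alignment = isTRUE(pair_result$no_alignment),
    dnds = NA_real_, syn_subs = NA_real_, syn_sites = NA_real_,
    nonsyn_subs = NA_real_, nonsyn_sites = NA_real_,
    a = NA_integer_, e = NA_real_, i = NA_integer_, hr = NA_real_,
    excluded = NA,
    stringsAsFactors = FALSE)
  if (!is.null(dnds)) {
    row$dnds <- dnds$dnds
    row$syn_subs <- dnds$counts$syn_subs
    row$syn_sites <- dnds$counts$syn_sites
    row$nonsyn_subs <- dnds$counts$nonsyn_subs
    row$nonsyn_sites <- dnds$counts$nonsyn_sites
  }
  if (!is.null(recomb)) {
    row$a <- recomb$a
    row$e <- recomb$e
    row$i <- recomb$i
    row$hr <- recomb$hr
    row$excluded <- recomb$excluded
    if (!recomb$excluded && recomb$i > 0L) {
      row$identical_fraction_actual <- recomb$a / recomb$i
      row$identical_fraction_expected <- recomb$e / recomb$i
    } else {
      row$identical_fraction_actual <- NA_real_
      row$identical_fraction_expected <- NA_real_
    }
  }
  row
}
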