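# End-to-end convenience: compare every genome pair of a set and collect
# the per-pair summary table consumed by the delineation module.

#' Pairwise summaries for a set of genomes
#'
#' Runs [compare_genomes()] on every unordered pair and, optionally,
#' [pair_dnds()] and [enriched_identical_genes()], returning one summary
#' row per pair (ANI in percent; see [summarize_pair()]).
#'
#' @param genomes Named list of [genome()] objects (names ignored; genome
#'   ids are taken from the objects).
#' @param dnds Compute genome-wide dN/dS per pair (default `TRUE`).
#' @param recombination Compute enriched-identical-genes hr per pair
#'   (default `TRUE`).
#' @param min_aligned_nt,min_genes Filters passed to
#'   [enriched_identical_genes()].
#' @param ... Further arguments passed to [compare_genomes()].
#' @return `data.frame` of per-pair summary rows.
#' @export
pairwise_summaries <- function(genomes, dnds = TRUE, recombination = TRUE,
                               min_aligned_nt = 500L, min_genes = 1000L,
                               ...) {
  stopifnot(length(genomes) >= 2L)
  ids <- vapply(genomes, `[[`, character(1L), "genome_id")
  ord <- order(ids)
  genomes <- genomes[ord]
  ids <- ids[ord]
  rows <- list()
  for (p in seq_len(length(genomes) - 1L)) {
    for (q in (p + 1L):length(genomes)) {
      pr <- compare_genomes(genomes[[p]], genomes[[q]], codon = dnds, ...)
      dd <- NULL
      if (dnds && !isTRUE(pr$no_alignment)) {
        dd <- pair_dnds(pr)
      }
      rc <- if (recombination) {
        enriched_identical_genes(pr, min_aligned_nt = min_aligned_nt,
                                 min_genes = min_genes)
      } else {
        NULL
      }
      rows[[length(rows) + 1L]] <- summarize_pair(pr, dd, rc)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
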