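# Evolutionary statistics per genome pair: genome-wide dN/dS by
# Nei-Gojobori codon counting, and the enriched-identical-genes estimate of
# recent homologous recombination.

# ---- Nei-Gojobori tables --------------------------------------------------
# Site and substitution counts are precomputed once over the 64 codon
# indices (NA at stop codons) and cached.

perms_of <- function(n) {
  switch(as.character(n),
         "1" = matrix(1L, 1L, 1L),
         "2" = rbind(c(1L, 2L), c(2L, 1L)),
         "3" = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                     c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
}

nei_site_tables <- function() {
  if (!is.null(.pkg_cache$nei_sites)) {
    return(.pkg_cache$nei_sites)
  }
  aa <- aa_by_index()
  syn <- rep(NA_real_, 64L)
  for (idx in 1:64) {
    if (aa[idx] == "*") next
    b <- c((idx - 1L) %/% 16L, ((idx - 1L) %/% 4L) %% 4L, (idx - 1L) %% 4L)
    s <- 0
    for (pos in 1:3) {
      for (alt in 0:3) {
        if (alt == b[pos]) next
        nb <- b
        nb[pos] <- alt
        j <- codon_index(nb[1L], nb[2L], nb[3L])
        # changes to a stop codon count as nonsynonymous ("*" != aa[idx])
        if (aa[j] == aa[idx]) s <- s + 1
      }
    }
    syn[idx] <- s / 3
  }
  .pkg_cache$nei_sites <- list(syn = syn, nonsyn = 3 - syn)
  .pkg_cache$nei_sites
}

# Pathway-averaged substitution classification for one codon pair (indices).
# All orderings of the differing positions are enumerated; pathways passing
# through a stop codon are excluded, unless every pathway does, in which
# case all are used with stop-entering steps counted nonsynonymous.
nei_subs_one <- function(ia, ib) {
  if (ia == ib) {
    return(c(0, 0))
  }
  aa <- aa_by_index()
  ba <- c((ia - 1L) %/% 16L, ((ia - 1L) %/% 4L) %% 4L, (ia - 1L) %% 4L)
  bb <- c((ib - 1L) %/% 16L, ((ib - 1L) %/% 4L) %% 4L, (ib - 1L) %% 4L)
  diffpos <- which(ba != bb)
  pm <- perms_of(length(diffpos))
  n_path <- nrow(pm)
  syn <- numeric(n_path)
  nonsyn <- numeric(n_path)
  hit_stop <- logical(n_path)
  for (p in seq_len(n_path)) {
    cur <- ba
    for (pos in diffpos[pm[p, ]]) {
      nxt <- cur
      nxt[pos] <- bb[pos]
      j_cur <- codon_index(cur[1L], cur[2L], cur[3L])
      j_nxt <- codon_index(nxt[1L], nxt[2L], nxt[3L])
      if (aa[j_nxt] == "*") hit_stop[p] <- TRUE
      if (aa[j_nxt] == aa[j_cur]) {
        syn[p] <- syn[p] + 1
      } else {
        nonsyn[p] <- nonsyn[p] + 1
      }
      cur <- nxt
    }
  }
  use <- !hit_stop
  if (!any(use)) use <- rep(TRUE, n_path)
  c(mean(syn[use]), mean(nonsyn[use]))
}

nei_sub_tables <- function() {
  if (!is.null(.pkg_cache$nei_subs)) {
    return(.pkg_cache$nei_subs)
  }
  stops <- stop_by_index()
  sense <- which(!stops)
  syn <- matrix(NA_real_, 64L, 64L)
  nonsyn <- matrix(NA_real_, 64L, 64L)
  for (ia in sense) {
    for (ib in sense) {
      v <- nei_subs_one(ia, ib)
      syn[ia, ib] <- v[1L]
      nonsyn[ia, ib] <- v[2L]
    }
  }
  .pkg_cache$nei_subs <- list(syn = syn, nonsyn = nonsyn)
  .pkg_cache$nei_subs
}

check_sense_codon <- function(codon, arg = "codon") {
  if (!is.character(codon) || length(codon) != 1L ||
      !grepl("^[ACGT]{3}$", codon)) {
    stop(sprintf("%s must be a single 3-letter codon over {A,C,G,T}", arg))
  }
  if (is_stop_codon(codon)) {
    stop(sprintf("%s is a stop codon (%s)", arg, codon))
  }
  invisible(TRUE)
}

#' Nei-Gojobori synonymous/nonsynonymous site counts for one codon
#'
#' For each of the three codon positions, the synonymous fraction is the
#' number of the three possible single-base changes that leave the amino
#' acid unchanged, divided by 3; changes creating a stop codon count as
#' nonsynonymous. Site counts always sum to 3.
#'
#' @param codon A sense codon, e.g. `"TTT"`.
#' @return Named numeric vector `c(syn_sites=, nonsyn_sites=)`.
#' @examples
#' nei_sites("TTT")  # 1/3 synonymous, 8/3 nonsynonymous
#' @export
nei_sites <- function(codon) {
  check_sense_codon(codon)
  idx <- match(codon, codons_by_index())
  tab <- nei_site_tables()
  c(syn_sites = tab$syn[idx], nonsyn_sites = tab$nonsyn[idx])
}

#' Nei-Gojobori substitution counts between two codons
#'
#' Zero differences give `(0, 0)`; a single difference is classified
#' directly; for two or three differences the synonymous/nonsynonymous
#' change counts are averaged over all orderings of the differing positions,
#' excluding pathways that pass through a stop codon (if every pathway hits
#' a stop, all are used and stop-entering steps are counted nonsynonymous).
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric vector `c(syn_subs=, nonsyn_subs=)`; the two counts
#'   sum to the nucleotide Hamming distance of the codons.
#' @examples
#' nei_substitutions("TTT", "TTC")  # one synonymous change
#' @export
nei_substitutions <- function(codon_a, codon_b) {
  check_sense_codon(codon_a, "codon_a")
  check_sense_codon(codon_b, "codon_b")
  cods <- codons_by_index()
  tab <- nei_sub_tables()
  ia <- match(codon_a, cods)
  ib <- match(codon_b, cods)
  c(syn_subs = tab$syn[ia, ib], nonsyn_subs = tab$nonsyn[ia, ib])
}

# ---- genome-pair dN/dS ----------------------------------------------------

#' dN/dS ratio from summed Nei counts
#'
#' @param syn_subs,syn_sites,nonsyn_subs,nonsyn_sites Summed counts.
#' @return The ratio `(nonsyn_subs/nonsyn_sites) / (syn_subs/syn_sites)`,
#'   or `NA` when undefined (no synonymous substitutions, or zero sites).
#' @export
dnds_ratio <- function(syn_subs, syn_sites, nonsyn_subs, nonsyn_sites) {
  if (syn_subs <= 0 || syn_sites <= 0 || nonsyn_sites <= 0) {
    return(NA_real_)
  }
  (nonsyn_subs / nonsyn_sites) / (syn_subs / syn_sites)
}

#' Genome-wide dN/dS for a genome pair
#'
#' Sums Nei-Gojobori site and substitution counts over every codon column of
#' every reciprocal-best-hit gene alignment, then applies the proportion
#' ratio `(nonsynonymous substitutions / nonsynonymous sites) /
#' (synonymous substitutions / synonymous sites)`. Site counts per column
#' are the average of the two codons' counts. No multiple-hit correction is
#' applied by default; `correction = "jc"` applies a Jukes-Cantor style
#' correction to the two proportions before taking the ratio.
#'
#' When there are no synonymous substitutions the ratio is undefined and
#' reported as `NA` with `undefined = TRUE` (never coerced to 0 or Inf).
#'
#' @param pair_result A [compare_genomes()] result with codon alignments.
#' @param correction `"none"` (default) or `"jc"`.
#' @return An object of class `dnds_result`: list with `counts`
#'   (syn_sites, nonsyn_sites, syn_subs, nonsyn_subs), `dnds`, `undefined`,
#'   `n_genes`.
#' @export
pair_dnds <- function(pair_result, correction = c("none", "jc")) {
  correction <- match.arg(correction)
  stopifnot(inherits(pair_result, "genome_pair_result"))
  cc <- pair_result$codon_alignments
  cc <- cc[!vapply(cc, is.null, logical(1L))]
  if (isTRUE(pair_result$no_alignment) || length(cc) == 0L) {
    stop("pair result has no codon alignments")
  }
  cods <- codons_by_index()
  ia <- match(unlist(lapply(cc, `[[`, "codons_a"), use.names = FALSE), cods)
  ib <- match(unlist(lapply(cc, `[[`, "codons_b"), use.names = FALSE), cods)
  st <- nei_site_tables()
  sb <- nei_sub_tables()
  syn_sites <- sum((st$syn[ia] + st$syn[ib]) / 2)
  nonsyn_sites <- sum((st$nonsyn[ia] + st$nonsyn[ib]) / 2)
  syn_subs <- sum(sb$syn[cbind(ia, ib)])
  nonsyn_subs <- sum(sb$nonsyn[cbind(ia, ib)])

  if (correction == "none") {
    dnds <- dnds_ratio(syn_subs, syn_sites, nonsyn_subs, nonsyn_sites)
  } else {
    jc <- function(p) {
      if (p >= 0.75) return(NA_real_)
      -3 / 4 * log(1 - 4 * p / 3)
    }
    dn <- jc(nonsyn_subs / nonsyn_sites)
    ds <- jc(syn_subs / syn_sites)
    dnds <- if (is.na(dn) || is.na(ds) || ds <= 0) NA_real_ else dn / ds
  }
  structure(
    list(counts = list(syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
                       syn_subs = syn_subs, nonsyn_subs = nonsyn_subs),
         dnds = dnds, undefined = is.na(dnds), n_genes = length(cc)),
    class = "dnds_result"
  )
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("<dnds_result> %d genes; dN/dS = %s\n", x$n_genes,
              if (x$undefined) "undefined" else format(x$dnds, digits = 4)))
  invisible(x)
}

# ---- enriched identical genes --------------------------------------------

#' Expected number of identical genes under genome-wide ANI
#'
#' The chance that a gene alignment of length L is identical by chance is
#' `ani^L`; the expectation over a set of aligned genes is the sum of the
#' per-gene probabilities (equivalently, the mean per-gene probability times
#' the number of aligned genes).
#'
#' @param ani Genome-wide ANI as a fraction in (0, 1].
#' @param aligned_lengths Integer vector of per-gene aligned lengths (nt).
#' @return Expected number of identical genes.
#' @examples
#' expected_identical(0.99, 500)  # 0.99^500
#' @export
expected_identical <- function(ani, aligned_lengths) {
  if (!is.numeric(ani) || length(ani) != 1L || is.na(ani) ||
      ani <= 0 || ani > 1) {
    stop("ani must be a single fraction in (0, 1]")
  }
  sum(ani ^ aligned_lengths)
}

#' Enriched identical genes (recombination estimate hr)
#'
#' Filters the reciprocal-best-hit alignments of a genome pair to those with
#' at least `min_aligned_nt` aligned, counts the identical ones (a), the
#' number expected by chance from genome-wide ANI (e), and reports
#' `hr = (a - e) / i` over the i surviving alignments. Pairs with fewer than
#' `min_genes` surviving alignments are flagged `excluded` rather than
#' scored.
#'
#' @param pair_result A [compare_genomes()] result.
#' @param min_aligned_nt Minimum aligned length per gene (default 500 nt).
#' @param min_genes Minimum surviving gene count (default 1000).
#' @return An object of class `recombination_result`: list with `a`, `e`,
#'   `i`, `hr`, `excluded`.
#' @export
enriched_identical_genes <- function(pair_result, min_aligned_nt = 500L,
                                     min_genes = 1000L) {
  stopifnot(inherits(pair_result, "genome_pair_result"))
  if (isTRUE(pair_result$no_alignment)) {
    return(structure(list(a = NA_integer_, e = NA_real_, i = 0L,
                          hr = NA_real_, excluded = TRUE),
                     class = "recombination_result"))
  }
  al <- pair_result$alignments
  keep <- al$aligned_length >= min_aligned_nt
  i <- sum(keep)
  if (i < min_genes) {
    return(structure(list(a = NA_integer_, e = NA_real_, i = i,
                          hr = NA_real_, excluded = TRUE),
                     class = "recombination_result"))
  }
  a <- sum(al$is_identical[keep])
  e <- expected_identical(pair_result$ani, al$aligned_length[keep])
  structure(list(a = a, e = e, i = i, hr = (a - e) / i, excluded = FALSE),
            class = "recombination_result")
}

#' @export
print.recombination_result <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("<recombination_result> excluded (%d genes passed filter)\n",
                x$i))
  } else {
    cat(sprintf("<recombination_result> a=%d e=%.4g i=%d hr=%.4f\n",
                x$a, x$e, x$i, x$hr))
  }
  invisible(x)
}
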