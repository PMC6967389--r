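# Independent oracles used by the test suite. These deliberately use
# different algorithms from the package implementation: full enumeration of
# global alignments, and recursive enumeration of Nei mutational pathways.

# Exhaustive global-alignment score: recursion over every monotone
# alignment path (match/mismatch, gap-in-b, gap-in-a), scoring gaps as
# `gap_open` for the first residue of a run and `gap_extend` for each
# further residue. Feasible for short sequences only.
oracle_align_score <- function(a, b, submat, gap_open, gap_extend) {
  va <- strsplit(a, "", fixed = TRUE)[[1L]]
  vb <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(va)
  m <- length(vb)
  best <- -Inf
  rec <- function(i, j, prev, acc) {
    if (i == n && j == m) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    if (i < n && j < m) {
      rec(i + 1L, j + 1L, 1L, acc + submat[va[i + 1L], vb[j + 1L]])
    }
    if (i < n) {
      rec(i + 1L, j, 2L, acc - if (prev == 2L) gap_extend else gap_open)
    }
    if (j < m) {
      rec(i, j + 1L, 3L, acc - if (prev == 3L) gap_extend else gap_open)
    }
  }
  rec(0L, 0L, 0L, 0)
  best
}

oracle_nt_submat <- function() {
  m <- matrix(-1, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T")))
  diag(m) <- 1
  m
}

# Nei site counts by direct enumeration of the 9 single-base changes,
# straight off Biostrings::GENETIC_CODE.
oracle_nei_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  cv <- strsplit(codon, "", fixed = TRUE)[[1L]]
  syn <- 0
  for (pos in 1:3) {
    for (alt in setdiff(bases, cv[pos])) {
      mut <- cv
      mut[pos] <- alt
      if (gc[paste(mut, collapse = "")] == gc[codon]) {
        syn <- syn + 1
      }
    }
  }
  c(syn = syn / 3, nonsyn = 3 - syn / 3)
}

# Nei substitution classification by recursive enumeration of all orderings
# of the differing positions; pathways through stop codons are excluded
# unless all pathways hit one, in which case all are used with stop steps
# counted nonsynonymous.
oracle_nei_subs <- function(codon_a, codon_b) {
  gc <- Biostrings::GENETIC_CODE
  ca <- strsplit(codon_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(codon_b, "", fixed = TRUE)[[1L]]
  diffpos <- which(ca != cb)
  if (length(diffpos) == 0L) {
    return(c(syn = 0, nonsyn = 0))
  }
  paths <- list()
  walk <- function(cur, remaining, syn, nonsyn, hit_stop) {
    if (length(remaining) == 0L) {
      paths[[length(paths) + 1L]] <<- c(syn, nonsyn, hit_stop)
      return(invisible(NULL))
    }
    for (pos in remaining) {
      nxt <- cur
      nxt[pos] <- cb[pos]
      aa_cur <- gc[paste(cur, collapse = "")]
      aa_nxt <- gc[paste(nxt, collapse = "")]
      walk(nxt, setdiff(remaining, pos),
           syn + as.numeric(aa_nxt == aa_cur),
           nonsyn + as.numeric(aa_nxt != aa_cur),
           hit_stop || aa_nxt == "*")
    }
  }
  walk(ca, diffpos, 0, 0, FALSE)
  pm <- do.call(rbind, paths)
  use <- pm[, 3L] == 0
  if (!any(use)) use <- rep(TRUE, nrow(pm))
  c(syn = mean(pm[use, 1L]), nonsyn = mean(pm[use, 2L]))
}
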