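# Global alignment wrappers. Both aligners are optimal global
# (Needleman-Wunsch) alignments with affine gaps under the convention that
# the first residue of a gap costs the open penalty and each further residue
# the extension penalty.

blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}

nt_submat <- function(match = 1, mismatch = -1) {
  key <- sprintf("ntmat_%g_%g", match, mismatch)
  if (is.null(.pkg_cache[[key]])) {
    .pkg_cache[[key]] <- Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = TRUE)
  }
  .pkg_cache[[key]]
}

# Biostrings charges gapOpening + L*gapExtension for a gap of length L, so
# open/extend penalties in the "first residue costs `open`" convention map
# to gapOpening = open - extend, gapExtension = extend.
biostrings_gap <- function(open, extend) {
  c(opening = open - extend, extension = extend)
}

# Identity/coverage bookkeeping on a pair of aligned strings. Terminal gap
# columns (before the first / after the last column where both sequences
# have a base) are trimmed; internal gap columns count as mismatches.
alignment_stats <- function(aligned_a, aligned_b) {
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  both <- which(ca != "-" & cb != "-")
  if (length(both) == 0L) {
    return(list(aligned_length = 0L, matches = 0L, identity = NA_real_,
                bases_a = 0L, bases_b = 0L))
  }
  lo <- both[1L]
  hi <- both[length(both)]
  ta <- ca[lo:hi]
  tb <- cb[lo:hi]
  matches <- sum(ta == tb & ta != "-")
  list(aligned_length = hi - lo + 1L,
       matches = matches,
       identity = matches / (hi - lo + 1L),
       bases_a = sum(ta != "-"),
       bases_b = sum(tb != "-"))
}

#' Optimal global protein alignment (BLOSUM62, affine gaps)
#'
#' Needleman-Wunsch global alignment under the BLOSUM62 matrix with a -12
#' gap-open and -3 gap-extension penalty: the first residue of a gap costs
#' -12 and each additional residue -3.
#'
#' @param aa_a,aa_b Non-empty amino-acid strings over the 20 standard
#'   residues.
#' @param gap_open,gap_extend Positive penalties (defaults 12 and 3).
#' @return List with `aligned_a`, `aligned_b` (gapped strings) and `score`.
#' @export
global_protein_align <- function(aa_a, aa_b, gap_open = 12, gap_extend = 3) {
  for (s in list(aa_a, aa_b)) {
    if (!is.character(s) || length(s) != 1L || is.na(s) || nchar(s) == 0L) {
      stop("amino-acid inputs must be single non-empty strings")
    }
    if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", s)) {
      stop("non-standard amino-acid residue in input")
    }
  }
  gp <- biostrings_gap(gap_open, gap_extend)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(aa_a), Biostrings::AAString(aa_b),
    substitutionMatrix = blosum62(),
    gapOpening = gp[["opening"]], gapExtension = gp[["extension"]],
    type = "global")
  list(aligned_a = as.character(Biostrings::alignedPattern(pa)),
       aligned_b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Optimal global nucleotide alignment
#'
#' Needleman-Wunsch with match +1, mismatch -1 and affine gaps (first gap
#' residue -5, each additional -2 by default). Nucleotide identity is
#' matches over aligned columns after trimming terminal-gap columns;
#' internal gap columns count as mismatches.
#'
#' @param nt_a,nt_b Non-empty nucleotide strings over `{A,C,G,T}`.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return List with `aligned_a`, `aligned_b`, `score`, `identity`,
#'   `aligned_length`, `matches`, `coverage_a`, `coverage_b`.
#' @export
global_nt_align <- function(nt_a, nt_b, match = 1, mismatch = -1,
                            gap_open = 5, gap_extend = 2) {
  for (s in list(nt_a, nt_b)) {
    if (!is.character(s) || length(s) != 1L || is.na(s) || nchar(s) == 0L) {
      stop("nucleotide inputs must be single non-empty strings")
    }
    if (!grepl("^[ACGT]+$", s)) {
      stop("nucleotide inputs may only contain A, C, G, T")
    }
  }
  gp <- biostrings_gap(gap_open, gap_extend)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(nt_a), Biostrings::DNAString(nt_b),
    substitutionMatrix = nt_submat(match, mismatch),
    gapOpening = gp[["opening"]], gapExtension = gp[["extension"]],
    type = "global")
  aligned_a <- as.character(Biostrings::alignedPattern(pa))
  aligned_b <- as.character(Biostrings::alignedSubject(pa))
  st <- alignment_stats(aligned_a, aligned_b)
  list(aligned_a = aligned_a, aligned_b = aligned_b,
       score = Biostrings::score(pa),
       identity = st$identity,
       aligned_length = st$aligned_length,
       matches = st$matches,
       coverage_a = st$bases_a / nchar(nt_a),
       coverage_b = st$bases_b / nchar(nt_b))
}
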