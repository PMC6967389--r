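# Standard genetic code helpers shared by the IO, alignment, simulation and
# dN/dS modules. Codons are always DNA (T, not U), uppercase.

DNA_BASES <- c("A", "C", "G", "T")

codon_table <- function() {
  if (is.null(.pkg_cache$codon_table)) {
    gc <- Biostrings::GENETIC_CODE
    .pkg_cache$codon_table <- setNames(as.character(gc), names(gc))
  }
  .pkg_cache$codon_table
}

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 non-stop codons.
#' @export
sense_codons <- function() {
  ct <- codon_table()
  names(ct)[ct != "*"]
}

is_stop_codon <- function(codon) {
  unname(codon_table()[codon] == "*")
}

split_codons <- function(nt_seq) {
  n <- nchar(nt_seq)
  substring(nt_seq, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
}

#' Validate a coding sequence
#'
#' Returns `NULL` when `nt_seq` is a valid coding sequence, otherwise a
#' short reason string. Partial genes are allowed (no start/stop codon
#' requirement) but the frame must be intact and free of internal stops;
#' ambiguity codes are rejected because codon-level counting downstream is
#' undefined on them.
#'
#' @param nt_seq Single nucleotide string.
#' @param min_length Minimum accepted length in nt (default 60).
#' @return `NULL` if valid, otherwise a character reason.
#' @export
validate_cds <- function(nt_seq, min_length = 60L) {
  if (!is.character(nt_seq) || length(nt_seq) != 1L || is.na(nt_seq)) {
    return("not a single sequence string")
  }
  n <- nchar(nt_seq)
  if (n < min_length) {
    return(sprintf("shorter than %d nt", min_length))
  }
  if (n %% 3L != 0L) {
    return("length not a multiple of 3")
  }
  if (!grepl("^[ACGT]+$", nt_seq)) {
    return("contains characters outside {A,C,G,T}")
  }
  aa <- unname(codon_table()[split_codons(nt_seq)])
  stops <- which(aa == "*")
  if (length(stops) > 0L && any(stops < length(aa))) {
    return("internal in-frame stop codon")
  }
  NULL
}

#' Translate a coding sequence under the standard genetic code
#'
#' A terminal stop codon is stripped from the translation; an internal
#' in-frame stop codon is an error, as is any character outside `{A,C,G,T}`
#' or a length that is not a multiple of 3.
#'
#' @param nt_seq Single nucleotide string (uppercase DNA).
#' @return Amino-acid string.
#' @examples
#' translate_cds("ATGAAA")  # "MK"
#' translate_cds("TTTTAA")  # "F" (terminal stop stripped)
#' @export
translate_cds <- function(nt_seq) {
  if (!is.character(nt_seq) || length(nt_seq) != 1L || is.na(nt_seq) ||
      nchar(nt_seq) == 0L) {
    stop("nt_seq must be a single non-empty string")
  }
  if (nchar(nt_seq) %% 3L != 0L) {
    stop("coding sequence length must be a multiple of 3")
  }
  if (!grepl("^[ACGT]+$", nt_seq)) {
    stop("coding sequence may only contain A, C, G, T")
  }
  aa <- unname(codon_table()[split_codons(nt_seq)])
  stops <- which(aa == "*")
  if (length(stops) > 0L) {
    if (any(stops < length(aa))) {
      stop("internal in-frame stop codon")
    }
    aa <- aa[-length(aa)]
  }
  paste(aa, collapse = "")
}

# --- integer codon encoding used by the simulator and Nei tables ----------
# bases map to 0..3 in DNA_BASES order; codon index = 16*b1 + 4*b2 + b3 + 1

encode_seq <- function(nt_seq) {
  match(strsplit(nt_seq, "", fixed = TRUE)[[1L]], DNA_BASES) - 1L
}

decode_seq <- function(v) {
  paste(DNA_BASES[v + 1L], collapse = "")
}

codons_by_index <- function() {
  if (is.null(.pkg_cache$codons_by_index)) {
    g <- expand.grid(b3 = 0:3, b2 = 0:3, b1 = 0:3)
    .pkg_cache$codons_by_index <- paste0(
      DNA_BASES[g$b1 + 1L], DNA_BASES[g$b2 + 1L], DNA_BASES[g$b3 + 1L]
    )
  }
  .pkg_cache$codons_by_index
}

aa_by_index <- function() {
  if (is.null(.pkg_cache$aa_by_index)) {
    .pkg_cache$aa_by_index <- unname(codon_table()[codons_by_index()])
  }
  .pkg_cache$aa_by_index
}

stop_by_index <- function() {
  if (is.null(.pkg_cache$stop_by_index)) {
    .pkg_cache$stop_by_index <- aa_by_index() == "*"
  }
  .pkg_cache$stop_by_index
}

codon_index <- function(b1, b2, b3) {
  16L * b1 + 4L * b2 + b3 + 1L
}
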