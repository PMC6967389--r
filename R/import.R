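# Adapter for externally computed ANI tables (e.g. FastANI long format).

#' Import an external long-format ANI table
#'
#' Reads FastANI-style long output (query, reference, ANI and optionally
#' mapped/total fragment counts), drops self-comparisons, and averages
#' reciprocal comparisons into one row per unordered pair. The alignment
#' fraction is mapped fragments over total fragments when the fragment
#' columns are present. Pairs reported in one direction only are kept and
#' flagged.
#'
#' @param x `data.frame` or path to a headerless tab-separated file. The
#'   first five columns are taken as query, reference, ani,
#'   mapped_fragments, total_fragments (the last two optional).
#' @return `data.frame` with `genome_a`, `genome_b`, `ani` (percent),
#'   `alignment_fraction`, `one_direction`.
#' @export
import_external_ani <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- read.table(x, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x), ncol(x) >= 3L)
  d <- data.frame(query = as.character(x[[1L]]),
                  reference = as.character(x[[2L]]),
                  ani = as.numeric(x[[3L]]),
                  stringsAsFactors = FALSE)
  if (ncol(x) >= 5L) {
    d$alignment_fraction <- as.numeric(x[[4L]]) / as.numeric(x[[5L]])
  } else {
    d$alignment_fraction <- NA_real_
  }
  d <- d[d$query != d$reference, , drop = FALSE]
  if (nrow(d) == 0L) {
    return(data.frame(genome_a = character(0L), genome_b = character(0L),
                      ani = numeric(0L), alignment_fraction = numeric(0L),
                      one_direction = logical(0L)))
  }
  d$genome_a <- pmin(d$query, d$reference)
  d$genome_b <- pmax(d$query, d$reference)
  key <- paste(d$genome_a, d$genome_b, sep = "\r")
  agg <- lapply(split(d, key), function(g) {
    data.frame(genome_a = g$genome_a[1L], genome_b = g$genome_b[1L],
               ani = mean(g$ani),
               alignment_fraction = if (all(is.na(g$alignment_fraction)))
                 NA_real_ else mean(g$alignment_fraction, na.rm = TRUE),
               one_direction = nrow(g) == 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$genome_a, out$genome_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
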