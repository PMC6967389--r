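# Single-copy marker-gene benchmarking: per-marker identity matrices,
# F1-optimal thresholds against pair labels, the recoverability metric and
# prevalence/presence summaries.

#' Construct a marker set
#'
#' A marker set holds the sequences of one marker gene across genomes
#' (0, 1 or many copies per genome).
#'
#' @param marker_name Marker identifier.
#' @param sequences `data.frame` with `genome_id`, `gene_id`, `nt_seq`.
#' @return Object of class `marker_set`.
#' @export
marker_set <- function(marker_name, sequences) {
  stopifnot(is.character(marker_name), length(marker_name) == 1L,
            is.data.frame(sequences),
            all(c("genome_id", "gene_id", "nt_seq") %in% names(sequences)))
  structure(list(marker_name = marker_name, sequences = sequences),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %s: %d sequences in %d genomes\n",
              x$marker_name, nrow(x$sequences),
              length(unique(x$sequences$genome_id))))
  invisible(x)
}

#' Read a per-marker multi-FASTA
#'
#' Headers carry `genome_id|gene_id` (first `|`-delimited field is the
#' genome, the remainder the gene id; a header without `|` is used as both).
#'
#' @param path FASTA path.
#' @param marker_name Marker name; defaults to the file name stem.
#' @return A [marker_set()].
#' @export
read_marker_fasta <- function(path, marker_name = NULL) {
  if (is.null(marker_name)) {
    marker_name <- tools::file_path_sans_ext(basename(path))
  }
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- sub("\\s.*$", "", names(seqs))
  genome_id <- sub("\\|.*$", "", hdr)
  gene_id <- ifelse(grepl("\\|", hdr), sub("^[^|]*\\|", "", hdr), hdr)
  marker_set(marker_name,
             data.frame(genome_id = genome_id, gene_id = gene_id,
                        nt_seq = toupper(as.character(seqs)),
                        stringsAsFactors = FALSE))
}

#' Read an hmmsearch tabular output file
#'
#' Thin adapter for `hmmsearch --tblout` tables: returns the target (gene),
#' query (marker) and score columns; comment lines are skipped. The caller
#' maps gene ids back to sequences.
#'
#' @param path Path to a `--tblout`-style file.
#' @return `data.frame` with `gene_id`, `marker_name`, `score`.
#' @export
read_hmmsearch_tblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(gene_id = character(0L), marker_name = character(0L),
                      score = numeric(0L)))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  data.frame(gene_id = vapply(fields, `[[`, character(1L), 1L),
             marker_name = vapply(fields, `[[`, character(1L), 3L),
             score = as.numeric(vapply(fields, `[[`, character(1L), 6L)),
             stringsAsFactors = FALSE)
}

pick_representatives <- function(ms, rule = "longest") {
  s <- ms$sequences
  s$len <- nchar(s$nt_seq)
  s <- s[order(s$genome_id, -s$len, s$gene_id), , drop = FALSE]
  s[!duplicated(s$genome_id), , drop = FALSE]
}

#' Pairwise marker identity matrix over genomes
#'
#' One representative sequence per genome is chosen (default: the longest,
#' ties broken by lexicographic gene id) and all representative pairs are
#' globally aligned; identities are reported in percent. Genomes lacking
#' the marker are absent from the matrix.
#'
#' @param ms A [marker_set()].
#' @param rule Representative choice rule (only `"longest"` implemented).
#' @return Symmetric identity matrix (percent) with 100 on the diagonal.
#' @export
marker_identity_matrix <- function(ms, rule = "longest") {
  stopifnot(inherits(ms, "marker_set"))
  reps <- pick_representatives(ms, rule)
  ids <- sort(reps$genome_id)
  if (length(ids) < 2L) {
    stop(sprintf("marker %s present in fewer than 2 genomes",
                 ms$marker_name))
  }
  reps <- reps[match(ids, reps$genome_id), , drop = FALSE]
  n <- length(ids)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (p in seq_len(n - 1L)) {
    for (q in (p + 1L):n) {
      al <- global_nt_align(reps$nt_seq[p], reps$nt_seq[q])
      m[p, q] <- m[q, p] <- 100 * al$identity
    }
  }
  m
}

#' Marker-gene recoverability
#'
#' The number of assembled copies of a marker gene divided by the number of
#' filtered (binned) genomes from the same metagenomes. A value above 1
#' means the marker captures organisms whose genomes were not recovered.
#'
#' @param n_assembled_genes Number of assembled marker gene copies.
#' @param n_filtered_genomes Number of filtered genomes (>= 1).
#' @return The recoverability quotient.
#' @examples
#' recoverability(300, 100)  # 3
#' @export
recoverability <- function(n_assembled_genes, n_filtered_genomes) {
  if (n_filtered_genomes < 1) {
    stop("n_filtered_genomes must be at least 1")
  }
  if (n_assembled_genes < 0) {
    stop("n_assembled_genes must be non-negative")
  }
  n_assembled_genes / n_filtered_genomes
}

#' Filter markers by prevalence
#'
#' Retains markers found in at least `min_fraction` of the genome universe
#' (closed boundary: exactly 85% is retained).
#'
#' @param markers Named list of [marker_set()] objects.
#' @param genomes Character vector: the genome universe.
#' @param min_fraction Minimum carrier fraction (default 0.85).
#' @return The retained subset of `markers`.
#' @export
prevalence_filter <- function(markers, genomes, min_fraction = 0.85) {
  stopifnot(length(genomes) > 0L)
  keep <- vapply(markers, function(ms) {
    carriers <- length(intersect(unique(ms$sequences$genome_id), genomes))
    carriers / length(genomes) >= min_fraction
  }, logical(1L))
  markers[keep]
}

#' Presence flags for markers in a second genome universe
#'
#' A marker is flagged present when it occurs in at least `min_fraction` of
#' the given universe (e.g. archaeal genomes, default 80%).
#'
#' @param markers Named list of [marker_set()] objects.
#' @param genomes Character vector: the genome universe.
#' @param min_fraction Minimum carrier fraction (default 0.80).
#' @return `data.frame` with `marker_name`, `carrier_fraction`, `present`.
#' @export
presence_summary <- function(markers, genomes, min_fraction = 0.80) {
  stopifnot(length(genomes) > 0L)
  frac <- vapply(markers, function(ms) {
    length(intersect(unique(ms$sequences$genome_id), genomes)) /
      length(genomes)
  }, numeric(1L))
  data.frame(marker_name = vapply(markers, `[[`, character(1L),
                                  "marker_name"),
             carrier_fraction = unname(frac),
             present = unname(frac >= min_fraction),
             stringsAsFactors = FALSE)
}

marker_scan <- function(ms, labels, ...) {
  m <- marker_identity_matrix(ms)
  off <- m[upper.tri(m)]
  if (max(off) - min(off) < 1e-9) {
    # a constant matrix predicts one class at every threshold
    stop(sprintf("marker %s: identities are constant across genomes",
                 ms$marker_name))
  }
  carriers <- rownames(m)
  lab <- labels[labels$genome_a %in% carriers &
                  labels$genome_b %in% carriers, , drop = FALSE]
  scan_thresholds(m, lab, ...)
}

#' Benchmark marker genes for species delineation
#'
#' For each marker: builds the pairwise identity matrix over carrier
#' genomes, scans identity thresholds against the pair labels restricted to
#' carriers, and reports the F1-optimal threshold, together with presence
#' and multiple-copy percentages over the genome universe. Markers with
#' fewer than 2 carriers, or whose restricted labels collapse to a single
#' class, are returned flagged without scores.
#'
#' When `labels` (and `markers`) are lists over several genome sets, the
#' per-threshold F1 is averaged across the sets where the marker is
#' scorable and the reported optimal threshold maximizes that average.
#'
#' @param markers Named list of [marker_set()] objects, or a list of such
#'   lists (one per genome set).
#' @param labels Pair labels `data.frame`, or a list of them parallel to
#'   `markers`.
#' @param genomes Genome universe (character vector), or a list of such.
#' @param archaeal_presence Optional named logical vector (marker name ->
#'   presence in archaea), e.g. from [presence_summary()].
#' @return `data.frame` with one row per marker: `marker_name`,
#'   `optimal_threshold`, `f1`, `presence_pct`, `multicopy_pct`,
#'   `archaeal_presence`, `flagged`.
#' @export
marker_benchmark <- function(markers, labels, genomes,
                             archaeal_presence = NULL) {
  if (is.data.frame(labels)) {
    markers_sets <- list(markers)
    labels_sets <- list(labels)
    genomes_sets <- list(genomes)
  } else {
    markers_sets <- markers
    labels_sets <- labels
    genomes_sets <- genomes
    stopifnot(length(markers_sets) == length(labels_sets),
              length(labels_sets) == length(genomes_sets))
  }
  marker_names <- sort(unique(unlist(lapply(markers_sets, names))))

  rows <- lapply(marker_names, function(mn) {
    pres <- multi_pct <- numeric(0L)
    f1_curves <- list()
    grid <- NULL
    for (s in seq_along(markers_sets)) {
      uni <- genomes_sets[[s]]
      ms <- markers_sets[[s]][[mn]]
      if (is.null(ms)) next
      counts <- table(factor(ms$sequences$genome_id, levels = uni))
      pres <- c(pres, 100 * mean(counts >= 1L))
      multi_pct <- c(multi_pct, 100 * mean(counts >= 2L))
      sc <- tryCatch(marker_scan(ms, labels_sets[[s]]),
                     error = function(e) NULL)
      if (!is.null(sc)) {
        f1_curves[[length(f1_curves) + 1L]] <- sc$table$f1
        grid <- sc$table$threshold
      }
    }
    if (length(f1_curves) == 0L) {
      return(data.frame(marker_name = mn, optimal_threshold = NA_real_,
                        f1 = NA_real_,
                        presence_pct = if (length(pres)) mean(pres)
                          else NA_real_,
                        multicopy_pct = if (length(multi_pct))
                          mean(multi_pct) else NA_real_,
                        archaeal_presence = NA, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    avg_f1 <- Reduce(`+`, f1_curves) / length(f1_curves)
    maxf <- max(avg_f1)
    at_max <- which(avg_f1 >= maxf - 1e-12)
    data.frame(marker_name = mn,
               optimal_threshold = (grid[min(at_max)] +
                                      grid[max(at_max)]) / 2,
               f1 = maxf,
               presence_pct = mean(pres),
               multicopy_pct = mean(multi_pct),
               archaeal_presence = if (!is.null(archaeal_presence) &&
                                         mn %in% names(archaeal_presence))
                 unname(archaeal_presence[mn]) else NA,
               flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
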