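# Population-level summaries: pair labels, recall/precision/F1 threshold
# scanning, the ANI x alignment-fraction density landscape, and binned
# median curves of per-pair metrics against ANI.

all_pairs <- function(ids) {
  ids <- sort(ids)
  n <- length(ids)
  if (n < 2L) {
    return(data.frame(genome_a = character(0L), genome_b = character(0L)))
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(genome_a = ids[idx[, "row"]], genome_b = ids[idx[, "col"]],
             stringsAsFactors = FALSE)
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Pair labels from a taxonomy table
#'
#' @param labels `data.frame` with columns `genome_id` and `species_id`,
#'   one row per genome.
#' @return `data.frame` over all unordered genome pairs with columns
#'   `genome_a`, `genome_b`, `same_species`, `source`.
#' @export
pair_labels_from_taxonomy <- function(labels) {
  stopifnot(is.data.frame(labels),
            all(c("genome_id", "species_id") %in% names(labels)))
  if (anyDuplicated(labels$genome_id)) {
    stop("each genome must have exactly one label")
  }
  if (anyNA(labels$species_id)) {
    stop("missing species label")
  }
  pairs <- all_pairs(labels$genome_id)
  sp <- setNames(labels$species_id, labels$genome_id)
  pairs$same_species <- unname(sp[pairs$genome_a] == sp[pairs$genome_b])
  pairs$source <- "taxonomy"
  pairs
}

#' Pair labels from 95% genome-wide ANI
#'
#' @param pair_summaries `data.frame` with `genome1`/`genome2` (or
#'   `genome_a`/`genome_b`) and `ani` on the 0-100 scale; pairs flagged
#'   `no_alignment` (or with `NA` ANI) are labelled different species.
#' @param cutoff Same-species cutoff in percent (default 95); the boundary
#'   is closed (`ani >= cutoff` is same species).
#' @return `data.frame` with `genome_a`, `genome_b`, `same_species`,
#'   `source`.
#' @export
pair_labels_from_ani <- function(pair_summaries, cutoff = 95.0) {
  d <- normalize_pair_df(pair_summaries)
  ani <- d$ani
  if ("no_alignment" %in% names(d)) {
    ani[which(d$no_alignment)] <- -Inf
  }
  ani[is.na(ani)] <- -Inf
  data.frame(genome_a = pmin(d$genome_a, d$genome_b),
             genome_b = pmax(d$genome_a, d$genome_b),
             same_species = ani >= cutoff,
             source = "ani95",
             stringsAsFactors = FALSE)
}

normalize_pair_df <- function(d) {
  stopifnot(is.data.frame(d))
  nm <- names(d)
  if (all(c("genome1", "genome2") %in% nm)) {
    d$genome_a <- d$genome1
    d$genome_b <- d$genome2
  }
  stopifnot(all(c("genome_a", "genome_b") %in% names(d)))
  d
}

#' Recall, precision and F1 from confusion counts
#'
#' `recall = tp/(tp+fn)`, `precision = tp/(tp+fp)`,
#' `f1 = 2 * recall * precision / (recall + precision)`. Any 0/0 gives a
#' score of 0 with `flagged = TRUE`.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return List with `recall`, `precision`, `f1`, `flagged`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0) {
    stop("counts must be non-negative")
  }
  flagged <- FALSE
  if (tp + fn == 0) {
    recall <- 0; flagged <- TRUE
  } else {
    recall <- tp / (tp + fn)
  }
  if (tp + fp == 0) {
    precision <- 0; flagged <- TRUE
  } else {
    precision <- tp / (tp + fp)
  }
  if (recall + precision == 0) {
    f1 <- 0; flagged <- TRUE
  } else {
    f1 <- 2 * (recall * precision) / (recall + precision)
  }
  list(recall = recall, precision = precision, f1 = f1, flagged = flagged)
}

#' Scan identity thresholds for species delineation accuracy
#'
#' For every threshold on the grid (default 80 to 100 percent in steps of
#' 0.1, 201 values), genome pairs at least as similar as the threshold are
#' predicted same-species and scored against the labels with recall,
#' precision and F1. The optimal threshold is reported as the midpoint of
#' the max-F1 plateau, together with the plateau bounds.
#'
#' @param identity Square identity matrix (percent, genome ids as
#'   dimnames) or long `data.frame` with `genome_a`, `genome_b`,
#'   `identity` columns.
#' @param labels Pair labels as from [pair_labels_from_taxonomy()] or
#'   [pair_labels_from_ani()].
#' @param lo,hi,step Threshold grid in percent.
#' @return Object of class `threshold_scan`: list with `table` (threshold,
#'   recall, precision, f1), `optimal_threshold`, `optimal_f1`,
#'   `plateau_lo`, `plateau_hi`.
#' @export
scan_thresholds <- function(identity, labels, lo = 80.0, hi = 100.0,
                            step = 0.1) {
  if (is.matrix(identity)) {
    ids <- rownames(identity)
    stopifnot(!is.null(ids), identical(ids, colnames(identity)))
    pr <- all_pairs(ids)
    pr$identity <- identity[cbind(pr$genome_a, pr$genome_b)]
    identity <- pr
  }
  identity <- normalize_pair_df(identity)
  stopifnot("identity" %in% names(identity))
  m <- match(pair_key(labels$genome_a, labels$genome_b),
             pair_key(identity$genome_a, identity$genome_b))
  if (anyNA(m)) {
    stop("identity values missing for some labeled pairs")
  }
  idv <- identity$identity[m]
  same <- labels$same_species
  if (all(same) || !any(same)) {
    stop("labels contain a single class; F1 is undefined for the task")
  }

  n_steps <- round((hi - lo) / step)
  grid <- round(lo + step * (0:n_steps), 10)
  scores <- vapply(grid, function(t) {
    pred <- idv >= t - 1e-9
    tp <- sum(pred & same)
    fp <- sum(pred & !same)
    fn <- sum(!pred & same)
    s <- precision_recall_f1(tp, fp, fn)
    c(s$recall, s$precision, s$f1)
  }, numeric(3L))
  tab <- data.frame(threshold = grid, recall = scores[1L, ],
                    precision = scores[2L, ], f1 = scores[3L, ])
  maxf <- max(tab$f1)
  at_max <- which(tab$f1 >= maxf - 1e-12)
  plateau_lo <- grid[min(at_max)]
  plateau_hi <- grid[max(at_max)]
  structure(
    list(table = tab,
         optimal_threshold = (plateau_lo + plateau_hi) / 2,
         optimal_f1 = maxf,
         plateau_lo = plateau_lo, plateau_hi = plateau_hi,
         n_pairs = length(idv), n_same = sum(same)),
    class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf(
    "<threshold_scan> %d pairs (%d same-species); optimal %.2f%% (plateau %.1f-%.1f), F1 %.4f\n",
    x$n_pairs, x$n_same, x$optimal_threshold, x$plateau_lo, x$plateau_hi,
    x$optimal_f1))
  invisible(x)
}

scott_bandwidth <- function(x, floor_bw = 0.5) {
  n <- length(x)
  bw <- sd(x) * n^(-1 / 6)
  if (!is.finite(bw) || bw < 1e-8) bw <- floor_bw
  bw
}

#' ANI x alignment-fraction density landscape
#'
#' Gaussian kernel density estimate of the per-pair (ANI, alignment
#' fraction) cloud on a regular grid, both axes in percent. Bandwidths
#' default to Scott's rule per axis (`sd * n^(-1/6)`), with a 0.5
#' percentage-point floor for degenerate inputs. Self-comparisons must not
#' be present in the input.
#'
#' @param pair_summaries `data.frame` with `ani` (percent) and
#'   `alignment_fraction` (fraction in `[0,1]` or percent; values <= 1.5
#'   are treated as fractions and rescaled).
#' @param n_grid Grid points per axis (default 101).
#' @param bandwidth Optional length-2 override of the kernel standard
#'   deviations (percent).
#' @return Object of class `landscape_grid`: list with `ani`, `af` (grid
#'   axes), `density` (matrix integrating to ~1 over the grid),
#'   `bandwidth`, `n`.
#' @export
ani_landscape <- function(pair_summaries, n_grid = 101L, bandwidth = NULL) {
  d <- pair_summaries[!is.na(pair_summaries$ani), , drop = FALSE]
  if (nrow(d) < 2L) {
    stop("at least 2 pairs with defined ANI are required")
  }
  x <- d$ani
  y <- d$alignment_fraction
  if (max(y, na.rm = TRUE) <= 1.5) {
    y <- 100 * y
  }
  bw <- if (is.null(bandwidth)) {
    c(scott_bandwidth(x), scott_bandwidth(y))
  } else {
    rep(bandwidth, length.out = 2L)
  }
  lims <- c(min(x) - 3.5 * bw[1L], max(x) + 3.5 * bw[1L],
            min(y) - 3.5 * bw[2L], max(y) + 3.5 * bw[2L])
  # MASS::kde2d uses h/4 as the kernel standard deviation
  k <- MASS::kde2d(x, y, h = 4 * bw, n = n_grid, lims = lims)
  structure(list(ani = k$x, af = k$y, density = k$z,
                 bandwidth = bw, n = length(x)),
            class = "landscape_grid")
}

#' Binned median curve of a per-pair metric against ANI
#'
#' Pairs are binned by ANI (default 0.5 percentage-point bins); each bin
#' reports the median of the metric over pairs where it is defined, with a
#' seeded percentile-bootstrap 95% confidence interval of the median. Bins
#' with fewer than `min_n` defined values are masked.
#'
#' @param pair_summaries `data.frame` with `ani` (percent) and the metric
#'   column; rows with `NA` metric (undefined dN/dS, excluded hr) are
#'   omitted from their bin.
#' @param metric One of `"dnds"`, `"hr"`, `"identical_fraction_actual"`,
#'   `"identical_fraction_expected"`, or any numeric column name present.
#' @param bin_width Bin width in percentage points (default 0.5).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param min_n Minimum defined values per bin (default 3).
#' @return Object of class `binned_curve`: `data.frame` with `bin_lo`,
#'   `bin_mid`, `median`, `ci_lo`, `ci_hi`, `n`, `masked`.
#' @export
binned_median_curve <- function(pair_summaries, metric = "dnds",
                                bin_width = 0.5, n_boot = 1000L,
                                seed = 1L, min_n = 3L) {
  stopifnot(metric %in% names(pair_summaries),
            "ani" %in% names(pair_summaries))
  d <- pair_summaries[!is.na(pair_summaries$ani) &
                        !is.na(pair_summaries[[metric]]), , drop = FALSE]
  if (nrow(d) == 0L) {
    stop(sprintf("metric '%s' is not defined for any pair", metric))
  }
  lo0 <- floor(min(d$ani) / bin_width) * bin_width
  hi0 <- ceiling(max(d$ani) / bin_width) * bin_width
  edges <- seq(lo0, max(hi0, lo0 + bin_width), by = bin_width)
  bin <- findInterval(d$ani, edges, rightmost.closed = TRUE)
  out <- withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_len(length(edges) - 1L), function(b) {
      v <- d[[metric]][bin == b]
      n <- length(v)
      if (n < min_n) {
        return(data.frame(bin_lo = edges[b], bin_mid = edges[b] +
                            bin_width / 2, median = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_, n = n,
                          masked = TRUE))
      }
      med <- median(v)
      bm <- vapply(seq_len(n_boot), function(i) {
        median(v[sample.int(n, n, replace = TRUE)])
      }, numeric(1L))
      ci <- quantile(bm, c(0.025, 0.975), names = FALSE)
      data.frame(bin_lo = edges[b], bin_mid = edges[b] + bin_width / 2,
                 median = med, ci_lo = ci[1L], ci_hi = ci[2L], n = n,
                 masked = FALSE)
    })
    do.call(rbind, rows)
  })
  class(out) <- c("binned_curve", "data.frame")
  out
}
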