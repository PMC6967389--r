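test_that("pair labels follow taxonomy and the 95% ANI rule", {
  labs <- data.frame(genome_id = c("g1", "g2", "g3"),
                     species_id = c("x", "x", "y"))
  pl <- pair_labels_from_taxonomy(labs)
  expect_equal(nrow(pl), 3L)
  expect_equal(pl$same_species[pl$genome_a == "g1" & pl$genome_b == "g2"],
               TRUE)
  expect_equal(sum(pl$same_species), 1L)

  all_same <- pair_labels_from_taxonomy(
    data.frame(genome_id = c("a", "b", "c"), species_id = "s"))
  expect_true(all(all_same$same_species))
  all_diff <- pair_labels_from_taxonomy(
    data.frame(genome_id = c("a", "b", "c"), species_id = c("1", "2", "3")))
  expect_false(any(all_diff$same_species))
  expect_error(pair_labels_from_taxonomy(
    data.frame(genome_id = c("a", "a"), species_id = c("1", "2"))),
    "exactly one")

  summ <- data.frame(genome1 = c("a", "a", "b"),
                     genome2 = c("b", "c", "c"),
                     ani = c(96.0, 94.9, 95.0),
                     no_alignment = FALSE)
  pa <- pair_labels_from_ani(summ)
  expect_equal(pa$same_species, c(TRUE, FALSE, TRUE))  # >= is closed
})

test_that("precision_recall_f1 follows the printed formulas", {
  s <- precision_recall_f1(8, 0, 2)
  expect_equal(s$recall, 0.8)
  expect_equal(s$precision, 1.0)
  expect_equal(s$f1, 2 * (0.8 * 1) / 1.8)
  z <- precision_recall_f1(0, 0, 0)
  expect_equal(c(z$recall, z$precision, z$f1), c(0, 0, 0))
  expect_true(z$flagged)
  p <- precision_recall_f1(10, 0, 0)
  expect_equal(p$f1, 1.0)
  expect_error(precision_recall_f1(-1, 0, 0), "non-negative")
})

test_that("scan_thresholds matches a brute-force rescan", {
  withr::with_seed(19, {
    n <- 12
    ids <- sprintf("g%02d", 1:n)
    sp <- rep(c("s1", "s2", "s3"), each = 4)
    m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    for (p in 1:(n - 1)) {
      for (q in (p + 1):n) {
        m[p, q] <- m[q, p] <- if (sp[p] == sp[q]) runif(1, 96, 99.5)
          else runif(1, 82, 91)
      }
    }
    diag(m) <- 100
    labs <- pair_labels_from_taxonomy(
      data.frame(genome_id = ids, species_id = sp))
    sc <- scan_thresholds(m, labs)
    expect_equal(nrow(sc$table), 201L)

    # independent rescan: re-derive tp/fp/fn per threshold from scratch
    for (row in c(1, 50, 101, 150, 201)) {
      t <- sc$table$threshold[row]
      tp <- fp <- fn <- 0
      for (r in seq_len(nrow(labs))) {
        idv <- m[labs$genome_a[r], labs$genome_b[r]]
        pred <- idv >= t - 1e-9
        if (pred && labs$same_species[r]) tp <- tp + 1
        if (pred && !labs$same_species[r]) fp <- fp + 1
        if (!pred && labs$same_species[r]) fn <- fn + 1
      }
      rec <- if (tp + fn > 0) tp / (tp + fn) else 0
      pre <- if (tp + fp > 0) tp / (tp + fp) else 0
      f1 <- if (rec + pre > 0) 2 * rec * pre / (rec + pre) else 0
      expect_equal(sc$table$f1[row], f1, info = paste("threshold", t))
      expect_equal(sc$table$recall[row], rec)
      expect_equal(sc$table$precision[row], pre)
    }
    expect_equal(sc$optimal_f1, max(sc$table$f1))

    # F1 is invariant to genome relabeling/reordering
    perm <- sample(n)
    m2 <- m[perm, perm]
    labs2 <- pair_labels_from_taxonomy(
      data.frame(genome_id = ids[perm],
                 species_id = paste0("sp_", sp[perm])))
    sc2 <- scan_thresholds(m2, labs2)
    expect_equal(sc2$table$f1, sc$table$f1)

    # translation equivariance: +1 on identities shifts the plateau by +1
    m3 <- m - 1  # shift down so the plateau stays interior to the grid
    sc3 <- scan_thresholds(m3, labs)
    expect_equal(sc3$plateau_lo, sc$plateau_lo - 1)
    expect_equal(sc3$plateau_hi, sc$plateau_hi - 1)
  })
})

test_that("scan_thresholds rejects single-class label sets", {
  m <- matrix(c(100, 96, 96, 100), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  labs <- pair_labels_from_taxonomy(
    data.frame(genome_id = c("a", "b"), species_id = "s"))
  expect_error(scan_thresholds(m, labs), "single class")
})

test_that("ani_landscape normalizes and resolves separated clusters", {
  withr::with_seed(3, {
    d <- data.frame(
      ani = c(rnorm(60, 99, 0.3), rnorm(60, 85, 0.5)),
      alignment_fraction = c(rnorm(60, 0.95, 0.01), rnorm(60, 0.40, 0.02)))
  })
  L <- ani_landscape(d)
  dx <- diff(L$ani[1:2])
  dy <- diff(L$af[1:2])
  expect_equal(sum(L$density) * dx * dy, 1, tolerance = 0.01)
  expect_true(all(L$density >= 0))

  # two local maxima with a saddle between them
  peak_hi <- L$density[which.min(abs(L$ani - 99)), which.min(abs(L$af - 95))]
  peak_lo <- L$density[which.min(abs(L$ani - 85)), which.min(abs(L$af - 40))]
  mid <- L$density[which.min(abs(L$ani - 92)), which.min(abs(L$af - 67.5))]
  expect_lt(mid, peak_hi)
  expect_lt(mid, peak_lo)

  # invariant to permutation of input order
  L2 <- ani_landscape(d[sample(nrow(d)), ])
  expect_equal(L2$density, L$density, tolerance = 1e-12)

  expect_error(ani_landscape(d[1, , drop = FALSE]), "at least 2")
})

test_that("binned_median_curve computes medians, CIs and masking", {
  d <- data.frame(ani = c(rep(90.2, 5), 95.2, rep(97.2, 4)),
                  dnds = c(rep(0.2, 5), 0.5, c(0.1, 0.2, 0.3, 0.4)))
  bc <- binned_median_curve(d, "dnds", bin_width = 0.5, n_boot = 200,
                            seed = 4, min_n = 3)
  b90 <- bc[bc$bin_lo == 90.0, ]
  expect_equal(b90$median, 0.2)
  expect_equal(c(b90$ci_lo, b90$ci_hi), c(0.2, 0.2))  # constant bin
  b95 <- bc[bc$bin_lo == 95.0, ]
  expect_true(b95$masked)  # n = 1 < min_n
  b97 <- bc[bc$bin_lo == 97.0, ]
  expect_equal(b97$median, 0.25)
  expect_true(b97$ci_lo <= b97$median && b97$median <= b97$ci_hi)

  # undefined metric values are omitted from their bin
  d2 <- d
  d2$dnds[1:3] <- NA
  bc2 <- binned_median_curve(d2, "dnds", bin_width = 0.5, n_boot = 50,
                             seed = 4, min_n = 1)
  expect_equal(bc2$n[bc2$bin_lo == 90.0], 2L)

  # deterministic given the seed
  bc3 <- binned_median_curve(d, "dnds", bin_width = 0.5, n_boot = 200,
                             seed = 4, min_n = 3)
  expect_identical(bc, bc3)
})
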