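test_that("nei_sites matches enumeration of single-base changes", {
  s <- nei_sites("TTT")
  expect_equal(unname(s), c(1 / 3, 8 / 3))
  expect_equal(unname(nei_sites("ATG")), c(0, 3))
  # every sense codon: counts sum to 3 and equal the oracle
  for (codon in sense_codons()) {
    got <- nei_sites(codon)
    expect_equal(sum(got), 3)
    expect_equal(unname(got), unname(oracle_nei_sites(codon)),
                 info = codon)
  }
  expect_error(nei_sites("TAA"), "stop")
  expect_error(nei_sites("AT"), "3-letter")
})

test_that("nei_substitutions classifies pathway-averaged changes", {
  expect_equal(unname(nei_substitutions("TTT", "TTC")), c(1, 0))
  expect_equal(unname(nei_substitutions("TTT", "GTA")), c(0.5, 1.5))
  expect_equal(unname(nei_substitutions("AAA", "AAA")), c(0, 0))
  expect_error(nei_substitutions("TTT", "TGA"), "stop")
})

test_that("substitution counts conserve the codon Hamming distance", {
  withr::with_seed(7, {
    sense <- sense_codons()
    for (trial in 1:200) {
      ca <- sample(sense, 1)
      cb <- sample(sense, 1)
      v <- nei_substitutions(ca, cb)
      hd <- sum(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
      expect_equal(sum(v), hd, info = paste(ca, cb))
    }
  })
})

test_that("dnds_ratio follows the printed proportion formula", {
  expect_equal(dnds_ratio(20, 200, 10, 800), 0.125)
  expect_true(is.na(dnds_ratio(0, 200, 10, 800)))  # undefined, not 0/Inf
})

test_that("pair_dnds sums Nei counts over all codon columns", {
  # two genes whose differences are fully enumerable by hand: one gene
  # carries a single synonymous change (TTT -> TTC), the other is identical
  pre <- fixture_cds(10, seed = 71)
  post <- fixture_cds(10, seed = 72)
  other <- fixture_cds(25, seed = 73)
  ga <- fixture_genome("A", c(paste0(pre, "TTT", post), other),
                       c("g1", "g2"))
  gb <- fixture_genome("B", c(paste0(pre, "TTC", post), other),
                       c("g1", "g2"))
  pr <- compare_genomes(ga, gb, min_shared = 1)
  dd <- pair_dnds(pr)
  # one synonymous difference (TTT->TTC), zero nonsynonymous
  expect_equal(dd$counts$syn_subs, 1)
  expect_equal(dd$counts$nonsyn_subs, 0)
  # site conservation: summed sites equal 3 x codon columns
  ncol_total <- sum(vapply(pr$codon_alignments,
                           function(x) length(x$codons_a), integer(1)))
  expect_equal(dd$counts$syn_sites + dd$counts$nonsyn_sites,
               3 * ncol_total)
  expect_false(dd$undefined)  # syn_subs > 0 but dN = 0 -> dnds 0
  expect_equal(dd$dnds, 0)

  # identical genomes: undefined (no synonymous substitutions)
  pr_same <- compare_genomes(ga, ga, min_shared = 1)
  dd_same <- pair_dnds(pr_same)
  expect_true(dd_same$undefined)
  expect_true(is.na(dd_same$dnds))
})

test_that("expected_identical is ANI^L summed over genes", {
  expect_equal(expected_identical(1.0, c(500, 700, 900)), 3)
  expect_equal(expected_identical(0.99, 500), 0.99^500)
  expect_lt(expected_identical(0.90, 500), 1e-22)
  expect_error(expected_identical(0, 500), "fraction")
})

test_that("enriched_identical_genes applies the hr formula and filters", {
  # synthetic pair result with fully controlled alignments
  mk_pair <- function(n, n_ident, len, ani) {
    structure(list(
      genome_a = "A", genome_b = "B",
      alignments = data.frame(
        gene_a = sprintf("a%d", 1:n), gene_b = sprintf("b%d", 1:n),
        aligned_length = rep(len, n),
        is_identical = c(rep(TRUE, n_ident), rep(FALSE, n - n_ident))),
      codon_alignments = NULL, ani = ani, alignment_fraction = 1,
      n_genes_aligned = n, no_alignment = FALSE),
      class = "genome_pair_result")
  }
  pr <- mk_pair(1000, 50, 600, 0.97)
  rc <- enriched_identical_genes(pr)
  e_manual <- 1000 * 0.97^600
  expect_equal(rc$a, 50L)
  expect_equal(rc$e, e_manual)
  expect_equal(rc$i, 1000L)
  expect_equal(rc$hr, (50 - e_manual) / 1000)
  expect_false(rc$excluded)
  # hr bounds
  expect_gte(rc$hr, -rc$e / rc$i)
  expect_lte(rc$hr, 1)

  # short alignments are filtered out before counting
  pr2 <- mk_pair(1000, 50, 400, 0.97)
  rc2 <- enriched_identical_genes(pr2)
  expect_true(rc2$excluded)
  expect_equal(rc2$i, 0L)

  # fewer than min_genes surviving -> excluded flag, not an error
  pr3 <- mk_pair(500, 10, 600, 0.97)
  expect_true(enriched_identical_genes(pr3)$excluded)
  expect_false(enriched_identical_genes(pr3, min_genes = 100)$excluded)
})

test_that("hr recovers the transferred gene fraction on simulations", {
  errs <- vapply(1:4, function(s) {
    cfg <- pair_sim_config(n_genes = 200, gene_length_mean = 600,
                           divergence = 0.06, omega = 0.5,
                           n_transfers = 20, seed = 400 + s)
    sim <- simulate_genome_pair(cfg)
    pr <- compare_genomes(sim$genome_a, sim$genome_b, codon = FALSE)
    rc <- enriched_identical_genes(pr, min_genes = 100)
    keep <- pr$alignments$aligned_length >= 500
    n_tr <- sum(pr$alignments$gene_a[keep] %in%
                  sim$truth$transferred_gene_ids)
    abs(rc$hr - n_tr / rc$i)
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("estimated dN/dS increases with the simulated omega", {
  est <- vapply(c(0.1, 0.3, 1.0), function(om) {
    cfg <- pair_sim_config(n_genes = 80, gene_length_mean = 300,
                           divergence = 0.05, omega = om, seed = 55)
    sim <- simulate_genome_pair(cfg)
    pr <- compare_genomes(sim$genome_a, sim$genome_b)
    pair_dnds(pr)$dnds
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})
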