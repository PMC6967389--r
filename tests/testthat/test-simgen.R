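test_that("generate_ancestor is deterministic and emits valid CDS", {
  g1 <- generate_ancestor(10, 300, seed = 1)
  g2 <- generate_ancestor(10, 300, seed = 1)
  expect_identical(g1, g2)
  g3 <- generate_ancestor(10, 300, seed = 2)
  expect_false(identical(g1$genes$nt_seq, g3$genes$nt_seq))

  g_one <- generate_ancestor(1, 300, seed = 3)
  expect_equal(nrow(g_one$genes), 1L)

  for (s in g1$genes$nt_seq) {
    expect_null(validate_cds(s))
  }
  # lengths stay within +/-20% of the mean and are codon-aligned
  expect_true(all(g1$genes$length %% 3 == 0))
  expect_true(all(abs(g1$genes$length - 300) <= 0.2 * 300 + 3))
})

test_that("evolve_pair hits the divergence target exactly (Hamming oracle)", {
  cfg <- pair_sim_config(n_genes = 200, gene_length_mean = 300,
                         divergence = 0.05, omega = 0.3, seed = 7)
  sim <- simulate_genome_pair(cfg)
  expect_equal(hamming_identity(sim$genome_a, sim$genome_b),
               sim$truth$true_identity)
  expect_equal(sim$truth$true_identity,
               1 - sim$truth$n_subs / sim$truth$n_sites)
  # lineage genomes are valid CDS throughout
  expect_null(validate_cds(sim$genome_a$genes$nt_seq[1]))
  expect_null(validate_cds(sim$genome_b$genes$nt_seq[1]))
})

test_that("evolve_pair truth bookkeeping is internally consistent", {
  cfg <- pair_sim_config(n_genes = 50, gene_length_mean = 300,
                         divergence = 0.08, omega = 0.5, seed = 11)
  anc <- generate_ancestor(cfg$n_genes, cfg$gene_length_mean,
                           seed = cfg$seed)
  out <- evolve_pair(anc, cfg)
  tr <- out$truth
  expect_equal(tr$true_syn_subs + tr$true_nonsyn_subs, tr$n_subs)
  expect_equal(nrow(tr$changes), tr$n_subs)
  expect_equal(sum(tr$per_gene$n_subs), tr$n_subs)
  # recount syn/nonsyn along the logged change list with the Nei code
  # tables: replay each change against the evolving lineage sequences
  seqs <- list(a = strsplit(anc$genes$nt_seq, ""),
               b = strsplit(anc$genes$nt_seq, ""))
  names(seqs$a) <- names(seqs$b) <- anc$genes$gene_id
  gc <- Biostrings::GENETIC_CODE
  n_syn <- 0L
  for (r in seq_len(nrow(tr$changes))) {
    ch <- tr$changes[r, ]
    v <- seqs[[ch$lineage]][[ch$gene_id]]
    expect_identical(v[ch$pos], ch$from)
    cstart <- ch$pos - (ch$pos - 1) %% 3
    old_codon <- paste(v[cstart:(cstart + 2)], collapse = "")
    v[ch$pos] <- ch$to
    new_codon <- paste(v[cstart:(cstart + 2)], collapse = "")
    if (gc[new_codon] == gc[old_codon]) n_syn <- n_syn + 1L
    seqs[[ch$lineage]][[ch$gene_id]] <- v
  }
  expect_equal(n_syn, tr$true_syn_subs)
  # replayed sequences equal the emitted genomes
  expect_identical(vapply(seqs$a, paste, character(1), collapse = ""),
                   setNames(out$genome_a$genes$nt_seq,
                            anc$genes$gene_id))
  expect_identical(vapply(seqs$b, paste, character(1), collapse = ""),
                   setNames(out$genome_b$genes$nt_seq,
                            anc$genes$gene_id))
})

test_that("divergence 0 and omega 0 behave as degenerate limits", {
  anc <- generate_ancestor(20, 300, seed = 5)
  cfg0 <- pair_sim_config(n_genes = 20, gene_length_mean = 300,
                          divergence = 0, omega = 0.3, seed = 5)
  out0 <- evolve_pair(anc, cfg0)
  expect_identical(out0$genome_a$genes$nt_seq, anc$genes$nt_seq)
  expect_identical(out0$genome_b$genes$nt_seq, anc$genes$nt_seq)
  expect_equal(out0$truth$n_subs, 0L)

  cfg_syn <- pair_sim_config(n_genes = 20, gene_length_mean = 300,
                             divergence = 0.02, omega = 0, seed = 5)
  out_syn <- evolve_pair(anc, cfg_syn)
  expect_equal(out_syn$truth$true_nonsyn_subs, 0L)
  expect_gt(out_syn$truth$true_syn_subs, 0L)
})

test_that("apply_transfers overwrites whole genes with exact copies", {
  cfg <- pair_sim_config(n_genes = 40, gene_length_mean = 300,
                         divergence = 0.05, omega = 0.3,
                         n_transfers = 10, seed = 13)
  sim <- simulate_genome_pair(cfg)
  tr <- sim$truth
  expect_length(tr$transferred_gene_ids, 10L)
  sel <- match(tr$transferred_gene_ids, sim$genome_a$genes$gene_id)
  expect_identical(sim$genome_a$genes$nt_seq[sel],
                   sim$genome_b$genes$nt_seq[sel])
  # non-transferred genes untouched relative to the no-transfer run
  cfg0 <- pair_sim_config(n_genes = 40, gene_length_mean = 300,
                          divergence = 0.05, omega = 0.3,
                          n_transfers = 0, seed = 13)
  sim0 <- simulate_genome_pair(cfg0)
  non <- setdiff(sim$genome_a$genes$gene_id, tr$transferred_gene_ids)
  i <- match(non, sim$genome_b$genes$gene_id)
  expect_identical(sim$genome_b$genes$nt_seq[i],
                   sim0$genome_b$genes$nt_seq[i])

  # transfer of every gene makes the genomes identical
  cfg_all <- pair_sim_config(n_genes = 20, gene_length_mean = 300,
                             divergence = 0.05, omega = 0.3,
                             n_transfers = 20, seed = 3)
  sim_all <- simulate_genome_pair(cfg_all)
  expect_identical(sim_all$genome_a$genes$nt_seq,
                   sim_all$genome_b$genes$nt_seq)
})

test_that("simulator operations are deterministic given the seed", {
  cfg <- pair_sim_config(n_genes = 30, gene_length_mean = 300,
                         divergence = 0.04, omega = 0.4,
                         n_transfers = 5, seed = 21)
  s1 <- simulate_genome_pair(cfg)
  s2 <- simulate_genome_pair(cfg)
  expect_identical(s1$genome_a, s2$genome_a)
  expect_identical(s1$genome_b, s2$genome_b)
  expect_identical(s1$truth$changes, s2$truth$changes)

  spec <- population_spec(n_species = 2, genomes_per_species = 2,
                          n_genes = 10, seed = 9)
  p1 <- generate_population(spec)
  p2 <- generate_population(spec)
  expect_identical(p1$genomes, p2$genomes)
  expect_identical(p1$truth$identity, p2$truth$identity)
})

test_that("generate_population constructs the identity gap it promises", {
  spec <- population_spec(n_species = 3, genomes_per_species = 4,
                          n_genes = 25, gene_length_mean = 300,
                          within_identity_range = c(0.97, 0.995),
                          between_identity_max = 0.90, seed = 5)
  pop <- generate_population(spec)
  expect_equal(length(pop$genomes), 12L)
  labs <- pair_labels_from_taxonomy(pop$labels)
  expect_equal(nrow(labs), 66L)
  expect_equal(sum(labs$same_species), 18L)

  ids <- names(pop$genomes)
  same_sp <- setNames(pop$labels$species_id, pop$labels$genome_id)
  within <- between <- numeric(0)
  for (r in seq_len(nrow(labs))) {
    idv <- pop$truth$identity[labs$genome_a[r], labs$genome_b[r]]
    if (labs$same_species[r]) within <- c(within, idv)
    else between <- c(between, idv)
  }
  expect_true(all(within >= 0.97 & within <= 0.995))
  expect_true(all(between <= 0.90))
  expect_lt(max(between), min(within))

  # truth identity matrix is exact: brute-force Hamming on two pairs
  expect_equal(hamming_identity(pop$genomes[[1]], pop$genomes[[2]]),
               pop$truth$identity[ids[1], ids[2]])
  expect_equal(hamming_identity(pop$genomes[[1]], pop$genomes[[9]]),
               pop$truth$identity[ids[1], ids[9]])

  expect_error(population_spec(between_identity_max = 0.98,
                               within_identity_range = c(0.97, 0.995)))
})

test_that("write_simulation emits FASTA, labels and truth files", {
  dir <- tempfile()
  spec <- population_spec(n_species = 2, genomes_per_species = 2,
                          n_genes = 5, seed = 2)
  pop <- generate_population(spec)
  write_simulation(pop, dir)
  expect_true(file.exists(file.path(dir, "labels.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  fastas <- list.files(dir, pattern = "\\.fna$")
  expect_length(fastas, 4L)
  back <- read_gene_fasta(file.path(dir, fastas[1]))
  expect_equal(nrow(back$genes), 5L)
})
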