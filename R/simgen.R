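# Synthetic genome-pair and population simulator. Substitutions are placed
# at distinct sites (no multiple hits, no back mutation), so the realized
# pairwise identity recorded in the truth object is exact, and every
# accepted change is logged with its synonymous/nonsynonymous class.

#' Configuration for a simulated genome pair
#'
#' @param n_genes Number of genes (>= 1).
#' @param gene_length_mean Mean gene length in nt, a multiple of 3; gene
#'   lengths are drawn uniformly within +/-20% and rounded to codons.
#' @param divergence Target per-site substitution fraction between the two
#'   lineages, in `[0, 0.25]`.
#' @param omega Nonsynonymous acceptance ratio (> 0). For `omega <= 1`
#'   synonymous changes are always accepted and nonsynonymous ones with
#'   probability `omega`; for `omega > 1` the roles are scaled so
#'   acceptance probabilities stay in `[0, 1]`.
#' @param n_transfers Number of genes overwritten by horizontal transfer
#'   (0 <= n_transfers <= n_genes).
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return Object of class `pair_sim_config`.
#' @export
pair_sim_config <- function(n_genes, gene_length_mean = 300L,
                            divergence = 0.05, omega = 0.3,
                            n_transfers = 0L, seed = 1L) {
  stopifnot(n_genes >= 1L, gene_length_mean %% 3L == 0L,
            gene_length_mean >= 60L,
            divergence >= 0, divergence <= 0.25,
            omega >= 0, n_transfers >= 0L, n_transfers <= n_genes)
  structure(list(n_genes = as.integer(n_genes),
                 gene_length_mean = as.integer(gene_length_mean),
                 divergence = divergence, omega = omega,
                 n_transfers = as.integer(n_transfers),
                 seed = as.integer(seed)),
            class = "pair_sim_config")
}

#' Generate a random ancestor genome
#'
#' Genes are uniform-random strings of sense codons (no internal stops);
#' lengths are drawn uniformly within +/-20% of `gene_length_mean` and
#' rounded to multiples of 3. Deterministic given the seed.
#'
#' @param n_genes Number of genes.
#' @param gene_length_mean Mean gene length (nt, multiple of 3).
#' @param seed Integer seed.
#' @param genome_id Identifier for the generated genome.
#' @return A [genome()] object.
#' @export
generate_ancestor <- function(n_genes, gene_length_mean = 300L, seed = 1L,
                              genome_id = "ancestor") {
  stopifnot(n_genes >= 1L, gene_length_mean %% 3L == 0L,
            gene_length_mean >= 60L)
  withr::with_seed(as.integer(seed), {
    n_codons <- pmax(20L, round(runif(n_genes, 0.8, 1.2) *
                                  gene_length_mean / 3))
    sense <- sense_codons()
    nt <- vapply(n_codons, function(nc) {
      paste(sample(sense, nc, replace = TRUE), collapse = "")
    }, character(1L))
    genome(genome_id,
           data.frame(gene_id = sprintf("gene_%05d", seq_len(n_genes)),
                      nt_seq = nt, stringsAsFactors = FALSE))
  })
}

# Shared site-placement engine: evolves `genomes` (list of lists of integer
# gene vectors, one list per lineage) by accepting substitutions at
# positions drawn without replacement from `pool` until `target` changes
# are placed. Returns updated genomes plus the change log.
place_substitutions <- function(genomes, lens, cum, pool, target, omega) {
  aa_idx <- aa_by_index()
  stop_idx <- stop_by_index()
  n_pool <- length(pool)
  n_lineage <- length(genomes)
  p_syn <- if (omega > 1) 1 / omega else 1
  p_nonsyn <- min(1, omega)
  placed <- 0L
  max_attempts <- 200L * max(target, 1L) + 1000L
  attempts <- 0L
  log_lineage <- integer(target)
  log_gene <- integer(target)
  log_pos <- integer(target)
  log_from <- integer(target)
  log_to <- integer(target)
  log_syn <- logical(target)
  offsets <- c(0L, cum)
  while (placed < target) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("target divergence unreachable under acceptance constraints")
    }
    if (n_pool == 0L) {
      stop("site pool exhausted before reaching target divergence")
    }
    j <- sample.int(n_pool, 1L)
    pos <- pool[j]
    g <- findInterval(pos - 1L, cum) + 1L
    off <- pos - offsets[g]
    lin <- if (n_lineage == 1L) 1L else sample.int(n_lineage, 1L)
    vec <- genomes[[lin]][[g]]
    cur <- vec[off]
    new_base <- sample.int(4L, 1L) - 1L
    if (new_base == cur) next
    cstart <- off - (off - 1L) %% 3L
    c_old <- vec[cstart:(cstart + 2L)]
    c_new <- c_old
    c_new[off - cstart + 1L] <- new_base
    i_old <- codon_index(c_old[1L], c_old[2L], c_old[3L])
    i_new <- codon_index(c_new[1L], c_new[2L], c_new[3L])
    if (stop_idx[i_new]) next
    syn <- aa_idx[i_new] == aa_idx[i_old]
    p <- if (syn) p_syn else p_nonsyn
    if (p < 1 && runif(1L) > p) next
    genomes[[lin]][[g]][off] <- new_base
    placed <- placed + 1L
    log_lineage[placed] <- lin
    log_gene[placed] <- g
    log_pos[placed] <- off
    log_from[placed] <- cur
    log_to[placed] <- new_base
    log_syn[placed] <- syn
    pool[j] <- pool[n_pool]
    n_pool <- n_pool - 1L
  }
  list(genomes = genomes,
       changes = data.frame(lineage = log_lineage, gene = log_gene,
                            pos = log_pos,
                            from = DNA_BASES[log_from + 1L],
                            to = DNA_BASES[log_to + 1L],
                            synonymous = log_syn,
                            stringsAsFactors = FALSE),
       pool = pool[seq_len(n_pool)])
}

#' Evolve a genome pair from an ancestor
#'
#' The two lineages independently receive substitutions at distinct sites
#' (sampled without replacement over the whole genome, so no site is hit
#' twice and realized identity is exact). A candidate position and
#' replacement base are drawn; synonymous changes are accepted with
#' probability 1, nonsynonymous ones with probability `min(1, omega)` (for
#' `omega > 1` synonymous acceptance is scaled by `1/omega` instead);
#' changes creating internal stop codons are rejected and redrawn. Sampling
#' stops when the realized per-site difference equals the target divergence
#' (to the nearest placed substitution).
#'
#' @param ancestor A [genome()] object.
#' @param config A [pair_sim_config()].
#' @return List with `genome_a`, `genome_b` and `truth` (class
#'   `truth_record`): realized identity, synonymous/nonsynonymous
#'   substitution counts, Nei site counts on the ancestor, the full change
#'   log and per-gene substitution counts.
#' @export
evolve_pair <- function(ancestor, config) {
  stopifnot(inherits(ancestor, "genome"), inherits(config, "pair_sim_config"))
  enc <- lapply(ancestor$genes$nt_seq, encode_seq)
  lens <- lengths(enc)
  cum <- cumsum(lens)
  S <- sum(lens)
  D <- as.integer(round(config$divergence * S))

  res <- withr::with_seed(config$seed + 1L, {
    place_substitutions(list(a = enc, b = enc), lens, cum,
                        pool = seq_len(S), target = D,
                        omega = config$omega)
  })
  changes <- res$changes
  changes$gene_id <- ancestor$genes$gene_id[changes$gene]
  changes$lineage <- c("a", "b")[changes$lineage]

  st <- nei_site_tables()
  anc_idx <- unlist(lapply(enc, function(v) {
    m <- matrix(v, nrow = 3L)
    codon_index(m[1L, ], m[2L, ], m[3L, ])
  }), use.names = FALSE)
  true_syn_sites <- sum(st$syn[anc_idx])
  true_nonsyn_sites <- sum(st$nonsyn[anc_idx])

  per_gene <- data.frame(
    gene_id = ancestor$genes$gene_id,
    length = lens,
    n_subs = tabulate(changes$gene, nbins = length(enc)),
    syn_subs = tabulate(changes$gene[changes$synonymous],
                        nbins = length(enc)),
    stringsAsFactors = FALSE)
  per_gene$nonsyn_subs <- per_gene$n_subs - per_gene$syn_subs

  mk_genome <- function(gene_vecs, id) {
    genome(id, data.frame(gene_id = ancestor$genes$gene_id,
                          nt_seq = vapply(gene_vecs, decode_seq,
                                          character(1L)),
                          stringsAsFactors = FALSE))
  }
  truth <- structure(
    list(true_identity = 1 - D / S,
         n_sites = S,
         n_subs = D,
         true_syn_subs = sum(changes$synonymous),
         true_nonsyn_subs = sum(!changes$synonymous),
         true_syn_sites = true_syn_sites,
         true_nonsyn_sites = true_nonsyn_sites,
         true_dnds = dnds_ratio(sum(changes$synonymous), true_syn_sites,
                                sum(!changes$synonymous),
                                true_nonsyn_sites),
         per_gene = per_gene,
         changes = changes[, c("lineage", "gene_id", "pos", "from", "to",
                               "synonymous")],
         transferred_gene_ids = character(0L),
         config = config),
    class = "truth_record")
  list(genome_a = mk_genome(res$genomes$a, "sim_a"),
       genome_b = mk_genome(res$genomes$b, "sim_b"),
       truth = truth)
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf(
    "<truth_record> identity %.5f over %d sites; %d subs (%d syn, %d nonsyn); %d transferred genes\n",
    x$true_identity, x$n_sites, x$n_subs, x$true_syn_subs,
    x$true_nonsyn_subs, length(x$transferred_gene_ids)))
  invisible(x)
}

#' Overwrite genes in one lineage by horizontal transfer
#'
#' Chooses `n_transfers` genes uniformly without replacement and overwrites
#' genome B's copy with genome A's, so transferred genes compare at 100%
#' identity. The truth record's identity over non-transferred genes is
#' recomputed from the per-gene change counts.
#'
#' @param pair List with `genome_a`, `genome_b` (as from [evolve_pair()]).
#' @param truth The matching `truth_record`.
#' @param n_transfers Number of genes to transfer.
#' @param seed Integer seed.
#' @return List with updated `genome_a`, `genome_b`, `truth`.
#' @export
apply_transfers <- function(pair, truth, n_transfers, seed = 1L) {
  stopifnot(inherits(truth, "truth_record"),
            n_transfers >= 0L, n_transfers <= nrow(pair$genome_a$genes))
  if (n_transfers == 0L) {
    return(list(genome_a = pair$genome_a, genome_b = pair$genome_b,
                truth = truth))
  }
  gb <- pair$genome_b
  ids <- withr::with_seed(as.integer(seed), {
    sample(pair$genome_a$genes$gene_id, n_transfers)
  })
  sel <- match(ids, gb$genes$gene_id)
  src <- match(ids, pair$genome_a$genes$gene_id)
  gb$genes$nt_seq[sel] <- pair$genome_a$genes$nt_seq[src]
  gb$genes$aa_seq[sel] <- pair$genome_a$genes$aa_seq[src]
  truth$transferred_gene_ids <- sort(ids)
  pg <- truth$per_gene
  non <- !(pg$gene_id %in% ids)
  truth$true_identity <- 1 - sum(pg$n_subs[non]) / sum(pg$length[non])
  list(genome_a = pair$genome_a, genome_b = gb, truth = truth)
}

#' Simulate a genome pair end to end
#'
#' Convenience wrapper: ancestor generation, divergence, then horizontal
#' transfers, all seeded from `config$seed`.
#'
#' @param config A [pair_sim_config()].
#' @return List with `ancestor`, `genome_a`, `genome_b`, `truth`.
#' @export
simulate_genome_pair <- function(config) {
  stopifnot(inherits(config, "pair_sim_config"))
  anc <- generate_ancestor(config$n_genes, config$gene_length_mean,
                           seed = config$seed)
  pair <- evolve_pair(anc, config)
  out <- apply_transfers(pair, pair$truth, config$n_transfers,
                         seed = config$seed + 2L)
  list(ancestor = anc, genome_a = out$genome_a, genome_b = out$genome_b,
       truth = out$truth)
}

#' Specification of a synthetic multi-species population
#'
#' The construction guarantees an identity gap: all within-species pairwise
#' identities fall in `within_identity_range` and all between-species
#' identities are at most `between_identity_max`.
#'
#' @param n_species Number of species.
#' @param genomes_per_species Genomes per species.
#' @param n_genes,gene_length_mean Gene content of every genome.
#' @param within_identity_range Length-2 fractions `(lo, hi)`.
#' @param between_identity_max Fraction; must be below `lo`.
#' @param seed Integer seed.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(n_species = 3L, genomes_per_species = 4L,
                            n_genes = 100L, gene_length_mean = 300L,
                            within_identity_range = c(0.97, 0.995),
                            between_identity_max = 0.90, seed = 1L) {
  stopifnot(n_species >= 1L, genomes_per_species >= 1L,
            length(within_identity_range) == 2L,
            within_identity_range[1L] < within_identity_range[2L],
            within_identity_range[2L] <= 1,
            between_identity_max < within_identity_range[1L],
            between_identity_max > 0)
  structure(list(n_species = as.integer(n_species),
                 genomes_per_species = as.integer(genomes_per_species),
                 n_genes = as.integer(n_genes),
                 gene_length_mean = as.integer(gene_length_mean),
                 within_identity_range = within_identity_range,
                 between_identity_max = between_identity_max,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# change `count` sites of the encoded genome at the given global positions,
# avoiding stop codons (every position always has at least one valid
# replacement base)
mutate_at_positions <- function(enc, cum, positions) {
  aa_idx <- aa_by_index()
  stop_idx <- stop_by_index()
  offsets <- c(0L, cum)
  for (pos in positions) {
    g <- findInterval(pos - 1L, cum) + 1L
    off <- pos - offsets[g]
    vec <- enc[[g]]
    cur <- vec[off]
    cstart <- off - (off - 1L) %% 3L
    c_old <- vec[cstart:(cstart + 2L)]
    alts <- setdiff(0:3, cur)
    ok <- vapply(alts, function(b) {
      c_new <- c_old
      c_new[off - cstart + 1L] <- b
      !stop_idx[codon_index(c_new[1L], c_new[2L], c_new[3L])]
    }, logical(1L))
    choice <- alts[ok]
    newb <- if (length(choice) == 1L) choice else
      choice[sample.int(length(choice), 1L)]
    enc[[g]][off] <- newb
  }
  enc
}

#' Generate a multi-species population with known identity structure
#'
#' One root ancestor is generated; each species ancestor differs from the
#' root at `(1 - between_identity_max)/2` of sites, and each genome differs
#' from its species ancestor at a per-genome fraction drawn so that
#' within-species pairwise identities land in `within_identity_range`. All
#' mutated position sets are disjoint, so every pairwise identity is exact
#' and recorded in the truth object.
#'
#' @param spec A [population_spec()].
#' @return List of class `population_sim` with `genomes` (named list of
#'   [genome()] objects), `labels` (`data.frame` genome_id, species_id) and
#'   `truth` (true pairwise identity matrix plus per-genome site counts).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  withr::with_seed(spec$seed, {
    root <- generate_ancestor(spec$n_genes, spec$gene_length_mean,
                              seed = spec$seed, genome_id = "root")
    enc_root <- lapply(root$genes$nt_seq, encode_seq)
    lens <- lengths(enc_root)
    cum <- cumsum(lens)
    S <- sum(lens)

    n_sp <- spec$n_species
    n_per <- spec$genomes_per_species
    d_between <- round((1 - spec$between_identity_max) / 2 * S)
    lo <- spec$within_identity_range[1L]
    hi <- spec$within_identity_range[2L]
    u <- round(runif(n_sp * n_per, (1 - hi) / 2, (1 - lo) / 2) * S)
    total_needed <- n_sp * d_between + sum(u)
    if (total_needed > S) {
      stop(sprintf(
        "infeasible population: %d mutated sites needed but only %d sites",
        total_needed, S))
    }
    perm <- sample.int(S)
    cursor <- 0L
    take <- function(n) {
      out <- perm[(cursor + 1L):(cursor + n)]
      cursor <<- cursor + n
      out
    }

    genomes <- list()
    labels <- data.frame(genome_id = character(0L),
                         species_id = character(0L),
                         stringsAsFactors = FALSE)
    u_by_genome <- integer(0L)
    sp_of_genome <- integer(0L)
    gi <- 0L
    for (s in seq_len(n_sp)) {
      enc_sp <- if (d_between > 0L) {
        mutate_at_positions(enc_root, cum, take(d_between))
      } else {
        enc_root
      }
      for (g in seq_len(n_per)) {
        gi <- gi + 1L
        ug <- u[gi]
        enc_g <- if (ug > 0L) {
          mutate_at_positions(enc_sp, cum, take(ug))
        } else {
          enc_sp
        }
        gid <- sprintf("sp%02d_g%02d", s, g)
        genomes[[gid]] <- genome(
          gid, data.frame(gene_id = root$genes$gene_id,
                          nt_seq = vapply(enc_g, decode_seq, character(1L)),
                          stringsAsFactors = FALSE))
        labels <- rbind(labels, data.frame(
          genome_id = gid, species_id = sprintf("species_%02d", s),
          stringsAsFactors = FALSE))
        u_by_genome[gi] <- ug
        sp_of_genome[gi] <- s
      }
    }

    n_tot <- length(genomes)
    ids <- names(genomes)
    identity <- matrix(1, n_tot, n_tot, dimnames = list(ids, ids))
    for (p in seq_len(n_tot - 1L)) {
      for (q in (p + 1L):n_tot) {
        d <- u_by_genome[p] + u_by_genome[q]
        if (sp_of_genome[p] != sp_of_genome[q]) {
          d <- d + 2L * d_between
        }
        identity[p, q] <- identity[q, p] <- 1 - d / S
      }
    }
    structure(list(genomes = genomes, labels = labels,
                   truth = list(identity = identity,
                                sites_per_genome = u_by_genome,
                                between_sites_per_species = d_between,
                                n_sites = S),
                   spec = spec),
              class = "population_sim")
  })
}

#' Write a simulated pair or population to disk
#'
#' Emits one gene FASTA per genome, a `labels.tsv` (populations only) and a
#' `truth.json` with the configuration echo and ground truth.
#'
#' @param sim Result of [simulate_genome_pair()] or [generate_population()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(sim, "population_sim")) {
    for (g in sim$genomes) {
      write_gene_fasta(g, file.path(dir, paste0(g$genome_id, ".fna")))
    }
    write.table(sim$labels, file.path(dir, "labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    truth <- list(spec = unclass(sim$spec),
                  identity = sim$truth$identity,
                  n_sites = sim$truth$n_sites)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    write_gene_fasta(sim$genome_a, file.path(dir, "genome_a.fna"))
    write_gene_fasta(sim$genome_b, file.path(dir, "genome_b.fna"))
    truth <- unclass(sim$truth)
    truth$config <- unclass(truth$config)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
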