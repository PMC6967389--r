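Package: speciesgap
Title: Gene-Based Genome Comparison Metrics for Bacterial Species Delineation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-by-gene comparison of bacterial genomes and the population
    summaries used to study the bacterial species boundary. Computes
    reciprocal-best-hit gene alignments, length-weighted average nucleotide
    identity (ANI) and alignment fraction, genome-wide dN/dS by
    Nei-Gojobori codon counting, and an estimate of recent homologous
    recombination from the enrichment of identical genes over the number
    expected from genome-wide ANI. Includes F1-optimal species-threshold
    scanning against taxonomy or 95%-ANI pair labels, ANI-landscape density
    summaries, single-copy marker-gene benchmarking with the recoverability
    metric, and a deterministic synthetic-genome simulator that provides
    ground truth (divergence, synonymous/nonsynonymous substitution counts,
    transferred genes, species labels) for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
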