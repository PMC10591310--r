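Package: dsrscreen
Title: Genome-Resolved Screening, Typing and Directional Inference of the
    Dissimilatory Sulfur Metabolism (Dsr) Pathway
Version: 0.1.0
Authors@R:
    person("dsrscreen", "developers", email = "dsrscreen@example.org",
           role = c("aut", "cre"))
Description: Detects Dsr-pathway gene families in predicted proteomes by
    reference-seeded local alignment, classifies DsrAB into its three major
    phylogenetic types and DsrL into subclusters 1A/1B/2A/2B/2C by nearest
    typed references, applies gene-complement decision rules to infer the
    direction of dissimilatory sulfur metabolism (reductive, oxidative, or
    switchable) per locus and per genome, assesses sulfate- versus
    sulfite-reduction pathway completeness, aggregates gene presence at
    lineage level under GTDB-style taxonomy, and evaluates degenerate
    dsrAB-targeted PCR primer mixes in silico (IUPAC matching, mismatch
    budgets, clade coverage, amplicon finding). A deterministic synthetic
    data generator emits typed reference families, archetype genomes and
    primer-site datasets with ground truth so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
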