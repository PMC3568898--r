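Package: oryzaevol
Title: Comparative Molecular Evolution of African and Asian Rice Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative evolutionary analysis of the African
    cultivated rice Oryza glaberrima against the japonica and indica
    subspecies of Asian rice (Oryza sativa), with Sorghum bicolor as an
    outgroup. Implements shotgun-read quality control and consensus calling,
    windowed nucleotide-divergence profiles with transition/transversion
    ratios, lineage-specific substitution assignment by parsimony, synonymous
    and nonsynonymous distances by the modified Nei-Gojobori method with
    gamma-Poisson amino-acid distances and three-taxon least-squares branch
    lengths, splice-site substitution detection with intron coding-potential
    testing, perfect-microsatellite (SSR) detection and cross-genome
    polymorphism classification, and a log-likelihood-ratio G-test engine for
    contingency-table enrichment. A synthetic-data generator evolves three
    ingroup genomes and outgroup coding sequences on the known species
    topology with planted splice-site and microsatellite events and simulated
    phred-scored shotgun reads, providing ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
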