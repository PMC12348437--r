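Package: saltNAC
Title: Candidate-Gene Screening for Salt Tolerance in Hexaploid Wheat
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A candidate-gene screening pipeline for salt tolerance in a
    hexaploid (AABBDD) genome, built around the wheat NAC transcription-factor
    family. Catalogues domain-positive genes into homoeolog members with
    subgenome-aware nomenclature and tandem-duplication clusters; groups
    salt-stress RNA-seq time-course trajectories; derives relative salt-injury
    rates (RSIR) from root phenotypes under control and NaCl conditions; runs
    per-SNP linear-model association scans with principal-component covariates;
    builds gene-region haplotypes and tests them against phenotypes; and
    designs KASP allele-specific genotyping markers. A seeded synthetic-data
    generator emulates the study design (three subgenomes, homoeolog triads,
    tandem clusters, four expression-trajectory groups, a 114-accession
    two-haplotype panel) so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'sim-config.R'
    'sim-genome.R'
    'sim-expression.R'
    'sim-population.R'
    'io.R'
    'catalog.R'
    'expression.R'
    'association.R'
    'haplotype.R'
    'kasp.R'
    'pipeline.R'
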