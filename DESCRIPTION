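Package: relapsetrace
Title: Somatic Mutation Filtering, Signature Refitting and Clonal
    Trajectory Classification for Diagnosis-Relapse Leukemia Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal tumor/germline whole-genome studies of
    pediatric acute lymphoblastic leukemia and similar diagnosis-relapse
    designs: a deterministic somatic SNV/indel filter cascade (depth anomaly,
    allele-frequency floor, repeats, homopolymers, indel proximity,
    population databases), structural-variant filtering, 96-channel
    trinucleotide mutation catalogs with de novo signature extraction by
    non-negative matrix factorization and parsimonious reference-signature
    selection, non-coding regulatory hotspot detection by complete-linkage
    position clustering, a driver-gene rule engine, binomial-mixture
    subclonal reconstruction with clone-tree enumeration, and classification
    of clonal evolution trajectories (persistent, rising, founding).
    Includes a synthetic-data generator producing signature mixtures, clone
    trees with per-timepoint prevalences, read-count level variant tables
    and planted filter artifacts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
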