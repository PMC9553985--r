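Package: tcrscope
Title: Antigen-Specific T-Cell Repertoire Analysis with Calibrated CDR3 Classifiers
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing bulk TCR-beta sequencing repertoires and linked
    single-cell data around predicted antigen specificity. Reads ImmunoSEQ-style,
    AIRR-C and simple clonotype tables; computes diversity, clonality and public
    sharing; extracts enriched CDR3 k-mer motifs; trains Gaussian-process CDR3
    classifiers with false-positive-rate calibrated thresholds and multi-epitope
    panels (an in-silico tetramer sort); derives cohort-level biomarkers with
    cross-validated AUROC and Kaplan-Meier comparisons; calls clonal expansion and
    replacement between longitudinal samples with exact tests; and tests
    specificity-phenotype links in single-cell data (cluster enrichment,
    differential expression, exhaustion-fraction change, ligand-receptor
    permutation tests). Ships seeded synthetic-data generators so every stage is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    survival,
    withr,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan,
    kernlab
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
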