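Package: ccstools
Title: Multi-Tumor Genomic Analyses for CYLD Cutaneous Syndrome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-tumor skin-cancer cohorts such as
    CYLD cutaneous syndrome: builds pyrimidine-normalized 96-channel
    trinucleotide substitution catalogs from somatic mutation lists, fits
    mutational-signature exposures by non-negative least squares with
    bootstrap exceedance probabilities and top-confidence signature
    selection, partitions a patient's mutations across tumors into trunk
    and branch sets for metastasis tracking, enumerates co-occurring
    mutant clones and calls biallelic tumor-suppressor loss from
    allele-specific copy-number segments, and calls contiguous
    differentially methylated regions from beta-value matrices. Includes
    seeded synthetic-data generators with planted truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    ape,
    vcfR
Config/testthat/edition: 3
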