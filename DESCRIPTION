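Package: papclone
Title: Clonality Analysis of Breast Papillary Lesions from Copy-Number and
    Mutation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers whether paired breast lesions (intraductal papilloma and
    synchronous carcinoma components) are clonally related, from segmented
    copy-number log2-ratio profiles and targeted somatic mutation tables.
    Implements threshold-based copy-number alteration calling with size
    filters, shared-breakpoint matching at a configurable genomic tolerance,
    clonality indices from shared mutations weighted by background cohort
    frequencies, fraction-of-genome-altered and progression-biomarker
    scoring, cohort contingency statistics (exact tests, odds ratios with
    Woolf confidence intervals, rank tests), unsupervised clustering of
    copy-number profiles, and a seeded synthetic paired-lesion cohort
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
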