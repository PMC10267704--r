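Package: famrvar
Title: Family-Based Rare-Variant Prioritization and Case-Control Replication
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for family-based prioritization of rare protein-altering
    variants from annotated multi-sample VCFs and for replication of candidate
    variants in independent case-control cohorts. Implements a staged filter
    cascade (read-support quality, coding consequence, sharing among family
    index patients, population rarity, candidate-gene panel membership) with a
    per-stage count report; dominant-model carrier collapsing with Pearson
    chi-square or Fisher exact 2x2 tests selected by expected cell counts and
    Woolf confidence intervals for odds ratios; Montreal-classification
    cohort summaries; and a fully seeded synthetic cohort generator that
    emulates post-calling sequencing output with known truth, for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
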