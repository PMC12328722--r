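Package: ramedies
Title: Rare Disease Trio Cohort Prioritization of De Novo and Compound
    Heterozygous Candidate Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analytical cohort-level tests for recurrence of deleterious de
    novo and compound heterozygous variants in rare-disease trio cohorts.
    Per-variant deleteriousness scores and basepair-resolution germline
    mutation rates are combined into "mutational targets" that are uniform
    under the null, so gene-level recurrence significance follows from the
    Irwin-Hall sum-of-uniforms distribution mixed over a Poisson event
    count, with no permutations. Includes Cauchy combination across score
    predictors, constraint-weighted false discovery rate control, an
    individual-level compound heterozygous statistic, exact meta-analysis
    from deidentified per-gene summary statistics, trio variant ingestion
    and QC filters, and a synthetic-cohort simulator for calibration and
    power studies without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml
Config/testthat/edition: 3
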