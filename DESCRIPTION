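Package: ponsub
Title: Panel-of-Normals SNP Database Construction and Tumor VCF Subtraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a panel-of-normals (PoN) germline SNP database from VCF
    files of unrelated normal samples and subtracts it from tumor VCFs to
    remove population-specific germline variants that public catalogs such as
    dbSNP under-represent. Variants are merged across the normal cohort with
    per-sample recurrence and alt-allele read depth, retained when supported
    by at least five alt-supporting reads in any carrier or recurrent in at
    least four normal samples, then depleted against a known-SNP catalog and a
    known-somatic catalog. The retained set is persisted as a single-file
    SQLite database keyed by the allele-aware tuple (chromosome, position,
    reference allele, alternate allele), which also drives the subtraction of
    tumor VCF records. Companion summaries report the filtering funnel,
    cohort minor-allele-frequency spectrum, per-chromosome novelty versus a
    reference catalog, and annotation class/region breakdowns. A synthetic
    cohort generator with planted ground truth supports end-to-end testing,
    and a command-line interface exposes the build, subtract, summarize and
    simulate steps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    dplyr,
    optparse,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
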