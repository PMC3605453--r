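Package: karyolute
Title: Chromosome Copy-Number Diversity and Mitotic Segregation-Error
    Modelling for Aneuploid Tumours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying intratumour chromosome copy-number
    diversity in aneuploid tumours such as neuroblastoma. Provides
    readers and writers for mirrored B-allele-frequency (mBAF) segment
    tables, whole-chromosome copy-number profile tables and numerical
    ISCN karyotype strings; an allele-mixture model for estimating the
    fraction of tumour DNA carrying each genomic imbalance (abnormality
    content) with per-case prevalence spans; stochastic simulators of
    four mitotic segregation-error models (chromosome loss from
    tetraploidy, sequential sister-chromatid non-disjunction, and two
    tripolar-mitosis variants) with expected-prevalence statistics
    against observed copy-number profiles; a generational population
    model of chromosome loss and whole-genome duplication under
    viability selection; FISH signal-count heterogeneity scoring with
    control-derived significance thresholds; and seed-deterministic
    synthetic-data generators for every input format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
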