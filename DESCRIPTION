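Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pharmacovigilance screening pipeline for
    FAERS-style spontaneous adverse event reports: a synthetic report
    generator with planted drug-event signals, readers and cleaners for the
    quarterly "$"-delimited ASCII tables (deduplication to the latest case
    version, drug-name normalisation, primary-suspect filtering, MedDRA-style
    PT-to-SOC mapping), per-pair 2x2 contingency tables, four
    disproportionality statistics (reporting odds ratio, proportional
    reporting ratio with chi-square, the BCPNN information component with
    Bayesian shrinkage priors, and the unshrunk empirical Bayes geometric
    mean), a conjunctive four-method signal rule, cohort descriptives, and a
    reproducible reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
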