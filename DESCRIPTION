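Package: embryosplice
Title: Developmental Exon-Skipping Programs and Their Reactivation in Cancer
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying exon-skipping events coupled to
    embryonic development (embryonic-positive and embryonic-negative exons)
    via pathway-activity correlation, detecting their reactivation in tumor
    cohorts, testing protein-domain enrichment on genomic intervals, fitting
    a partial least squares regression of median embryonic-exon inclusion on
    splicing-factor expression to nominate critical splicing factors, running
    causal-validation statistics (expression-matched mutation effects,
    knockdown response, copy-number stratification), and applying a
    multi-evidence filter cascade for upstream transcription-factor
    regulators. Ships a synthetic-data generator with planted ground truth so
    the whole pipeline is testable end to end without external cohorts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
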