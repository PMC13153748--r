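Package: shareduse
Title: Referral Networks of Shared CT and MRI Use from Administrative Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects collaborative ("shared") use of CT and MRI equipment among
    medical facilities from long-format outpatient claims records, using a
    three-condition temporal rule: an isolated imaging examination at a target
    facility embedded within an ongoing course of visits at a source facility.
    Builds per-stratum (fiscal year by modality) weighted directed referral
    networks and computes density, dyadic reciprocity, Newman-Girvan modularity
    and Louvain communities, plus annual summary tables with nonparametric
    comparisons. Includes a seeded synthetic-claims generator with planted
    ground truth (events, rule violations, community structure) so that
    detection, network metrics and community recovery are testable without
    access to real insurance claims.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
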