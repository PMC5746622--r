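Package: sanops
Title: Anatomic Region Alerting and Terminology Utility Classification
    for Prior CT Imaging
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements SANOPS, a 17-region anatomic framework for issuing
    same/similar/proximate alerts when a computed tomography (CT) exam is
    ordered and relevant prior exams exist, together with an ordinal
    five-class scale scoring how much extra machinery a standard anatomic
    terminology (FMA, SNOMED CT, RadLex, LOINC, LOINC/RSNA Playbook style
    graphs) needs beyond SANOPS to support such alerts. Provides typed-edge
    terminology graph I/O and path analysis, minimal fixture terminologies
    encoding the structural facts the alerting scenarios depend on, random
    graph generators with planted utility classes, an alert engine over exam
    histories, and nonparametric comparison (Kruskal-Wallis, Wilcoxon
    rank-sum) of utility-class samples across terminologies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
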