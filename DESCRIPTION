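Package: asfscreen
Title: Spent-Media Interaction Screening and Functional Metagenome
    Coverage for Defined Gut Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the systems-level characterization of defined gut
    microbial consortia such as the altered Schaedler flora (ASF).
    Implements functional-ortholog (NOG) coverage analysis of metagenome
    collections with stratified random-consortium null models; growth-curve
    normalization and area-under-curve growth calling; NMR peak-integral
    z-score profiling against fresh media; classification of spent versus
    double-spent media transitions into the 18 growth-by-transition
    scenarios with detection of cross-feeding and emergent metabolism; and
    Jaccard genetic-versus-metabolic distance and ortholog-metabolite
    correlation analysis. A seeded synthetic-data generator emulates every
    input with planted ground truth so the full pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
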