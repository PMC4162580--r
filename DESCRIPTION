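Package: grnbench
Title: Benchmarking De Novo Gene Regulatory Network Reverse-Engineering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for benchmarking statistical
    reverse-engineering of transcriptional regulatory networks in budding
    yeast. Builds gold-standard networks of direct regulatory interactions by
    intersecting knockout-based regulatory evidence with ChIP binding
    evidence, runs a family of eighteen association-based inference
    approaches (bivariate screening and Generalized Local Learning with
    Fisher's Z or G2 conditional-independence tests, assembled with AND/OR
    rules), scores inferred networks with four core and three combined
    Euclidean accuracy metrics with hypergeometric significance, summarizes
    results with Pareto-frontier ROC curves, and tests the correlation
    between transcription-factor connectivity and sub-network reconstruction
    accuracy with an exact permutation test. A seeded synthetic-data
    generator emulates the four study designs (wild-type replicates,
    environment/time series, compendium, targeted perturbation) so the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
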