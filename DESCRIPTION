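Package: ecoextent
Title: Effect-Extent Estimation for Linear-Construction Impact on Plant
    Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the spatial extent of linear-construction impact
    (pipelines, roads, railways) on plant communities from belt-transect
    vegetation surveys. Computes importance values (relative density,
    frequency and cover) per species and belt transect, classifies species
    by a modified TWINSPAN (two-way indicator species analysis) with
    correspondence-analysis ordination and most-heterogeneous-cluster
    division order, aggregates clusters into integrated importance values,
    assigns disturbance response groups (promoted pioneers, suppressed
    original dominants, accompanying species), and locates the K-points
    where the group trajectories stabilise or cross, giving the effect
    extent and the edge-effect transition zone. Includes Shannon-Wiener,
    Pielou and Margalef community indices, a permutation test for
    indicator validation, survey-design builders, and a synthetic survey
    generator with known disturbance structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
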