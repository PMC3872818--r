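Package: heatnca
Title: Transcription Factor Activity Inference for Multi-Ecotype Heat
    Stress Transcriptomes via Network Component Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers hidden transcription factor activities from
    multi-ecotype heat-stress expression data. Provides per-ecotype
    differential-expression calling (Welch t-tests and two-way ANOVA
    genotype-by-treatment interaction), construction of a signed
    bipartite regulator-target network by correlation thresholding,
    Network Component Analysis (constrained alternating least squares
    decomposition of expression into control strengths with a fixed
    zero pattern and condition-specific activities), identifiability
    checking and network reduction, activity-profile classification,
    bootstrap-supported hierarchical clustering, hypergeometric gene-set
    over-representation tests, and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
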