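Package: actilipid
Title: Mood-Episode Detection from Wheel-Running Actigraphy and Brain
    Lipidomics Differential Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for long-term wheel-running actigraphy in mouse models of
    mood disorders and for companion brain-lipidomics analysis. Detects
    mania-like hyperactivity bouts (outlier-level running sustained for six
    hours or more) and depression-like hypoactivity episodes (two weeks or
    more of markedly reduced running) from binned revolution counts, computes
    a delayed-activity index quantifying circadian phase delay, and compares
    groups with rank tests and standardized effect sizes. The lipidomics arm
    performs per-lipid differential testing gated jointly on significance and
    Cohen's d, lipid-class and fatty-acid enrichment by Fisher's exact test,
    PCA, hierarchical clustering, OPLS-DA with top-fraction loading selection,
    and a two-factor analysis of Euclidean distances between lipid profiles.
    A synthetic-data module generates actigraphy and lipid tables with known
    ground truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    ape,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
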