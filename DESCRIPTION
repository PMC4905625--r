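Package: tuberquant
Title: Quantitative Histopathology of Cortical Tubers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Semi-automated quantification of DAB immunohistochemistry on
    slide images (tissue segmentation, positive-area fractions, optical
    density, size-gated cell counting, field-based giant-cell densities),
    a rule-based histological classifier of cortical tuber subtypes (A/B/C)
    in tuberous sclerosis complex surgical tissue, Ward hierarchical
    clustering of marker profiles, and the supporting statistics battery
    (Kruskal-Wallis with Dunn post hoc, Kendall and partial Kendall
    correlation, chi-square, multi-rater kappa with interpretation bands,
    BCa bootstrap). Includes a synthetic slide-phantom and cohort generator
    with exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    boot,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    withr,
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
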