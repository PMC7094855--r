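Package: woundCA
Title: Correspondence-Analysis Screening of Incised-Muscle Expression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for screening wound-age marker genes from microarray
    time courses of incised skeletal muscle. Implements flag-based feature
    quality control and four-step percentile normalization, one-way ANOVA with
    Tukey HSD post-hoc calling and a 27-category fluctuation taxonomy,
    an arctangent-degree transform of fold changes followed by correspondence
    analysis, geometric classification of the biplot into six fold-change
    ordering areas with fitted boundary lines, distance-based gene-set
    construction, and Fisher / PAGE gene-set enrichment. Ships a synthetic
    study generator with planted ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
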