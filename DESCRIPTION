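Package: digistress
Title: Quantification of Blue-Light (Digital Stress) Damage and Protection in Skin Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification procedures for assessing blue-light ("digital
    stress") damage and its pharmacological protection in in-vitro skin
    models: mitochondrial-network skeleton-graph metrics (trees, branches,
    lengths), micropattern single-cell spreading, immunostain color-index
    quantification, exposure-dose and molar arithmetic for
    crocin-to-crocetin conversion, day/night melatonin time-series
    comparison, and a Shapiro-gated statistical ladder with Dunnett and
    Mann-Whitney post-hoc routes. Ships synthetic-data generators with
    known ground truth so every stage is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    pracma,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
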