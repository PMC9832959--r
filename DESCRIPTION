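Package: gtscreen
Title: Image-Based High-Throughput Screening Analysis for Sex-Dimorphic
    Mesenchymal Proliferation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for image-based 384-well proliferation
    screens of genital tubercle mesenchyme (GTme) cells. Provides a
    seeded synthetic-data generator (plate layouts, well counts with
    planted compound effects, Hoechst-stained nuclei field images with
    ground truth, growth courses, qPCR Ct tables, BrdU regions of
    interest), nuclear segmentation and per-well counting, per-plate
    MAD-based hyper/hypo hit calling with negative-control false
    discovery estimation, hit categorisation on the count versus
    nuclear-size plane, sex-dimorphism partitioning, kinase-family
    enrichment by exact test, and the supporting quantifications
    (Welch t tests on growth curves, delta-delta-Ct expression, BrdU+
    density per unit area).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
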