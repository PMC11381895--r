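Package: dvpflow
Title: Image-Guided Cell Classification, Microdissection Geometry and
    Low-Input Proteomics Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale re-implementation of a deep visual proteomics
    (DVP) analysis chain for immunohistochemistry-guided tissue
    profiling: classification of segmented nuclei from RGB stain
    intensities and morphology, spatial quantification of cell classes
    across annotated tissue regions, laser-microdissection contour
    dilation and XML export, and a Perseus-style statistics stack for
    low-input label-free proteomics (valid-value filtering, downshifted
    normal imputation of missing-not-at-random values, s0-moderated t
    and ANOVA statistics with permutation-based FDR, coefficients of
    variation, hierarchical clustering, PCA, rank-abundance and
    hypergeometric over-representation). A synthetic-data module
    generates nuclei feature tables, region polygons and protein
    intensity matrices with planted ground truth so the whole pipeline
    is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
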