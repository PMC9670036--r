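Package: slidegraph
Title: Graph-Transformer Classification and Saliency Mapping for Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Slide-level classification of gigapixel pathology images via a
    graph-transformer. Slides are tiled into fixed-size patches, background
    patches are filtered by a brightness/saturation rule, and the kept
    patches are embedded with a contrastively pre-trained residual CNN.
    Patch embeddings and grid adjacency form a slide graph that is processed
    by graph convolution, min-cut pooling and a class-token transformer to
    predict the slide label. Class-specific saliency maps (GraphCAM) are
    derived from gradient-weighted attention relevance, reversed through the
    pooling assignment, and painted back onto the slide; localization is
    scored against annotation masks by intersection-over-union. Includes a
    synthetic-slide generator with planted lesions, an evaluation harness
    (per-class metrics, ROC/PR curves, stratified cross-validation), and a
    small reverse-mode automatic-differentiation engine that powers all
    model training on CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
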