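Package: tubulemorph
Title: Semi-Automatic Morphometry of Seminiferous Tubules by Livewire
    Boundary Tracing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-automatic measurement of seminiferous tubule cross-sections
    in stained testis micrographs. Edge evidence (multichannel vector
    gradient, Laplacian zero-crossings, Canny edges) is combined into a
    weighted link cost that drives a livewire (intelligent-scissors)
    minimum-cost boundary tracer between user seed points. Closed contours
    are converted to tubular area, tubular diameter and epithelial height in
    physical units. Includes a synthetic phantom generator with analytic
    ground truth, a study simulator with animal-level random effects, and
    the endpoint statistics used in testicular morphometry: one-way and
    hierarchical (nested random-effect) ANOVA with Tukey-adjusted pairwise
    comparisons and compact letter displays.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lmerTest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
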