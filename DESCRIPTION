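Package: monodec
Title: Discrete Exterior Calculus and Vertex-Model Mechanics for Cell Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Represents confluent epithelial monolayers as primal polygonal
    networks with triangulated duals and builds a discrete-exterior-calculus
    toolkit on them: signed incidence matrices and their reduced
    periphery-suppressed forms, Hodge stars, wedge products and musical
    isomorphisms valid without edge-link orthogonality, the sixteen
    grad/curl/div/rot operators and six Laplacians, and Helmholtz-Hodge
    decomposition with harmonic fields on multiply-connected (ablated)
    monolayers. Includes a quadratic-energy cell vertex model (growth by
    random division under peripheral stress, T1 transitions, ablation), the
    rotated force potential and per-cell stress tensors, and radial
    upper-bound scaling fits for the mechanical response to ablation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    tibble,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
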