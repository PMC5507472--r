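Package: fprate
Title: Fokker-Planck Derived Spike Rate Models for Adaptive
    Integrate-and-Fire Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reduction of large networks of adaptive exponential
    integrate-and-fire (aEIF) neurons to low-dimensional spike rate
    models via the Fokker-Planck mean-field equation. Provides the
    ground-truth Monte-Carlo network simulator, an implicit
    Scharfetter-Gummel finite-volume solver for the time-dependent
    Fokker-Planck system, a shooting/Magnus solver for the eigenvalue
    problem of the Fokker-Planck operator and its adjoint, Fourier-domain
    linear rate response functions with semi-analytic filter fits,
    precomputation of all input-moment dependent quantities on a lookup
    grid, time integration of four reduced rate models (two spectral,
    two linear-nonlinear cascade variants), and a benchmark harness that
    quantifies how well each reduction reproduces the network rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    igraph,
    deSolve
Config/testthat/edition: 3
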