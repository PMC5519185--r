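Package: lrpath
Title: Linear Response Path Following for Large Conformational Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Drives large conformational transitions of coarse-grained
    protein models with iteratively updated biasing forces derived from
    linear response theory. Provides a Langevin dynamics engine over
    elastic-network and double-basin potentials with steered and targeted
    restraints, covariance estimation from trajectory segments, motif-based
    perturbation designs, an iterative biased/unbiased cycling protocol, a
    trajectory-analysis metric suite (superposition RMSD, helix angles,
    contacts, salt bridges, occupancy grids, gate radius of gyration,
    RMSF), and a built-in two-state three-fold-symmetric toy membrane
    transporter that switches between outward-facing and inward-facing
    forms.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
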