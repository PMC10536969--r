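Package: autoabs
Title: Automatic Generation, Contraction and Pruning of Density-Fitting
    Auxiliary Basis Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates density-fitting (resolution-of-the-identity)
    auxiliary basis sets for an element from an arbitrary contracted
    spherical Gaussian orbital basis set.  Candidate auxiliary radial
    functions are enumerated from one-center orbital products, optionally
    prescreened and then selected per angular momentum by a pivoted
    Cholesky decomposition of the Coulomb-metric Gram matrix to a
    threshold tau.  The primitive auxiliary set is contracted through an
    eigendecomposition of the three-index-integral importance matrix to a
    threshold epsilon, and high-angular-momentum shells are pruned with
    element-dependent occupied-shell rules.  Reads and writes Gaussian94
    and Basis Set Exchange JSON basis-set files and reports size and
    accuracy diagnostics.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
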