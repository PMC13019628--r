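Package: lmf12
Title: Integral-Direct Local Explicitly Correlated MP2 (LMP2-F12)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An iteration-free, integral-direct implementation of local
    second-order Moller-Plesset perturbation theory with explicit electron
    correlation (LMP2-F12, ansatz 2B with fixed geminal amplitudes and a
    complementary auxiliary basis set).  Provides a McMurchie-Davidson
    Gaussian integral engine for the Coulomb and Slater-geminal operator
    family, density fitting with robust fitting for geminal integrals,
    Boys orbital localization and projected atomic orbitals,
    Boughton-Pulay correlation domains, Cholesky/Laplace factorization of
    orbital-energy denominators, per-domain CABS construction, and the
    local coupling-intermediate algorithm, together with a restricted
    Hartree-Fock reference provider and a command-line driver for small
    molecules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
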