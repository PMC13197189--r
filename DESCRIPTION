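Package: zulfsabre
Title: Symmetry-Reduced Simulation of SABRE Hyperpolarization at Zero and Ultralow Field
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates signal amplification by reversible exchange (SABRE)
    hyperpolarization experiments in the zero- to ultralow-field (ZULF) NMR
    regime. Coherent spin dynamics, random-fluctuating-field Redfield
    relaxation and reversible chemical exchange between the free substrate and
    the transient Ir-dihydride complex are integrated on an equal footing in
    Liouville space. Two exact symmetry reductions make multi-spin systems
    tractable: magnetically equivalent groups are replaced by effective spins
    with statistical weights, and the dynamics is restricted to the
    zero-quantum-coherence subspace of the total-spin-projection superoperator.
    Unreduced full-space and effective-spin-only reference solvers are included
    for validation, together with field-scan, free-induction-decay and
    J-spectrum simulation front ends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
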