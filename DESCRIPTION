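Package: thrombosim
Title: Plasma-Composition-Based Simulation of Thrombin Generation with a
    Protein C Pathway
Version: 0.1.0
Authors@R:
    person("Hemostasis", "Modeling Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mass-action kinetic simulation of tissue-factor-initiated
    thrombin generation from an individual's measured plasma coagulation
    factor composition (fII, fV, fVII, fVIII, fIX, fX, AT, TFPI, PC),
    extending the Hockin et al. (2002) extrinsic-cascade model with a
    protein C / thrombomodulin negative-feedback module.  Includes a stiff
    Rosenbrock integrator with analytic Jacobian, thrombogram parameter
    extraction (peak level and rate, their times, area under the curve,
    clot time), a cohort pipeline with inclusion filtering and
    group-stratified summaries, a synthetic-cohort and pedigree generator,
    and kinship-aware polygenic variance-component likelihood-ratio tests
    for group comparisons adjusted for age and sex.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
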