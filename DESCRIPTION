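Package: tarpgate
Title: Kinetic Modelling of AMPA Receptor-TARP Complex Gating and
    Superactivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of Markov kinetic schemes for AMPA-type
    glutamate receptors in complex with transmembrane AMPA receptor
    regulatory proteins (TARPs).  Implements a two-layer gating scheme in
    which the TARP switches between a basal and an active conformation,
    with channel opening promoting the active (superactive) state.  The
    package constructs and balances the schemes (microscopic
    reversibility via the Kolmogorov cycle criterion), integrates the
    master equation over piecewise-constant agonist concentration
    protocols (pulses, two-pulse recovery, trains), provides a stochastic
    single-channel oracle, fits the standard electrophysiological
    relaxation measures (multi-exponential decays, recovery curves,
    superactivation, charge transfer, Hill curves), reproduces the
    model-level predictions of the superactivation mechanism, and
    generates realistic synthetic patch-clamp traces for end-to-end
    validation of the analysis stack.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
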