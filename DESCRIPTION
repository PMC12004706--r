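Package: navstate
Title: State-Dependent Block of Voltage-Gated Sodium Channels: Simulation
    and Analysis of Automated Patch-Clamp Pharmacology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying state-dependent inhibition of voltage-gated
    sodium (Nav) channels in the modulated-receptor framework. Provides
    declarative voltage-clamp protocol builders (activation, steady-state
    fast and slow inactivation, use-dependence pulse trains, recovery from
    inactivation, block-kinetics), a seven-state continuous-time Markov
    simulator of Nav gating with resting- and inactivated-state drug
    binding that generates realistic peak-current sweep tables, the
    standard electrophysiology fitting primitives (Hill-Langmuir
    concentration-response, Boltzmann voltage dependence, mono- and
    bi-exponential time courses), and an analysis pipeline that resolves
    resting-state (K_R) and inactivated-state (K_I) dissociation constants
    from holding-potential-dependent apparent IC50 values via a four-state
    binding model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    minpack.lm,
    jsonlite,
    tibble,
    dplyr,
    readr,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
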