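Package: nmfield
Title: Next-Generation Neural Mass and Neural Field Models with Gap Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact mean-field models of synaptically and electrically coupled
    quadratic integrate-and-fire (QIF) neuron populations, and the spatially
    extended neural fields built from them.  Provides the microscopic spiking
    network simulator, the single-population (R, V, U) neural mass model and
    its two-population excitatory-inhibitory extension, the conformal map to
    the Kuramoto synchrony order parameter, delayed integro-differential
    neural field solvers on periodic 1D and 2D domains with balanced
    (inverted) wizard-hat connectivity, and linear stability tools for
    locating Hopf, Turing and Turing-Hopf instabilities of the spatially
    uniform state.  Includes attractor sweeps for bistability analysis,
    time-frequency observables (Morlet and short-time Fourier spectrograms,
    beta-band power, movement-related beta-rebound experiments), and simple
    YAML-configured command-line drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    signal,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
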