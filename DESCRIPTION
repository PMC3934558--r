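Package: ffgain
Title: Gain Control by Feedforward Inhibition in Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models gain control exerted by an inhibitory feedforward
    ("open-loop feedback") pathway on leaky integrate-and-fire neurons,
    as found in the electrosensory lateral-line lobe (ELL) of weakly
    electric fish. Provides closed-form (Siegert) and simulated f-I
    curves for the deep-pyramidal drive population and the superficial
    pyramidal target cell, classification of subtractive, divisive and
    non-monotonic gain-control regimes with the critical feedforward
    strength separating them, delay-induced linearization of f-I curves
    under low-pass-filtered time-varying stimuli, and a parameterized
    forward model of in-vivo ELL pyramidal-cell responses to amplitude
    modulations of the electric field.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
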