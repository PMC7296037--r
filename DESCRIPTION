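Package: gammaflicker
Title: Hippocampal Oscillation, Synaptic Plasticity and Vesicle-Release
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for studies of hippocampal low-gamma
    oscillations and CA3-CA1 synaptic plasticity after cerebral ischemia.
    Provides multitaper power spectral density estimation with Slepian
    (DPSS) tapers, band power and perievent spectrograms, theta-gamma
    phase-amplitude coupling (modulation index and comodulogram with
    surrogate nulls), exploration/approach PSD-ratio statistics, fEPSP
    slope and amplitude measurement with input-output curves,
    paired-pulse ratio and LTP quantification, FM1-43 destaining
    first-order kinetics, and seeded synthetic-data generators emulating
    local field potentials with tunable cross-frequency coupling, evoked
    fEPSP sweeps under a release-probability model, and punctum
    destaining traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    minpack.lm,
    pracma,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
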