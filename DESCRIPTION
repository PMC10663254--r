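Package: slowosc
Title: Up/Down State Detection and Evoked Response Analysis for In Vivo LFP
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of slow-oscillation local field potentials (LFP)
    recorded under deep anesthesia: multivariate Up/Down state detection
    combining the raw LFP, a log-scaled 200-1500 Hz power estimate (logMUA)
    and a gamma-variance envelope via principal component analysis and a
    bimodal Gaussian-mixture threshold; Welch power spectral density and
    band power; quantification of stimulus-evoked responses (trial
    averaging, baseline normalization, first positive/negative peak
    detection, transition times, amplitude, area under the curve,
    intensity-response curves, 600 ms long-lasting response metrics on
    multielectrode arrays); scalar quantifications (monosynaptic tracing
    normalization, dendritic spine density, Cavalieri volumes,
    microdialysis percent-of-baseline) and the Benjamini-Hochberg false
    discovery rate procedure. Includes a seeded synthetic-data simulator
    with exported ground truth so every stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    mclust,
    pracma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
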