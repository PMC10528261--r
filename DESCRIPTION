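Package: mwangio
Title: Microwave Angiography by Ultra-Wideband MIMO Radar Sounding
Version: 0.1.0
Authors@R:
    person("mwangio", "developers", email = "mwangio@example.org",
           role = c("aut", "cre"))
Description: Simulation and dynamic imaging toolkit for microwave
    angiography with an ultra-wideband (UWB) multiple-input
    multiple-output (MIMO) radar array. Provides a forward simulator of
    M-sequence radar returns from a cylindrical tissue phantom containing
    pulsating artery surrogates, and the imaging pipeline that localizes
    the arteries from their pulsation: slow-time background subtraction,
    range-Doppler (slow-time FFT) reduction to the pulsation-frequency
    channel matrix, coherent and incoherent delay-and-sum beamforming,
    adaptive (Wiener-type) post-filtering, M-mode time-series extraction
    and peak-detection scoring against known artery positions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
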