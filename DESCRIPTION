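Package: swrgamma
Title: Sharp Wave-Ripple Detection and Gamma-Induced Network Plasticity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for hippocampal local field potential (LFP)
    recordings in which gamma-oscillation episodes are interposed between
    quiet states rich in sharp wave-ripple (SWR) complexes. Implements
    dual-criterion SWR detection (a voltage threshold at mean plus six
    standard deviations of the event-free ripple-band recording, followed by
    a complex Morlet wavelet spectral criterion at mean plus one standard
    deviation of event-free cutout coefficients), event delimitation at
    sharp-wave local minima, per-event quantification (area, amplitude,
    duration, ripple count and frequency), spectral characterization of
    theta-nested gamma episodes (Welch and averaged-FFT spectra, peak power
    and frequency, power-by-duration exposure), paired pre/post-gamma
    plasticity statistics (exact Wilcoxon signed-rank, Spearman correlation,
    normalization, percentage change), and excitatory/inhibitory
    postsynaptic-current charge analysis. A synthetic-data generator
    produces LFP and current traces with ground-truth annotations so every
    stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
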