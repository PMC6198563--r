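Package: emgcoh
Title: Intramuscular EMG Coherence, H-Reflex Suppression and Force Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired surface-EMG recordings and
    stimulus-locked reflex sweeps. Estimates disjoint-segment autospectra,
    cross-spectra, coherence, phase and cumulant density with independence-null
    confidence limits; pools coherence across records within a group and
    compares groups per frequency with a variance-stabilised chi-squared
    difference-of-coherence test; summarises alpha- and beta-band coherence
    areas; quantifies functional reciprocal inhibition as soleus H-reflex
    suppression at dorsiflexion onset (normalised to the maximal M-response);
    and computes maximal-torque, rate-of-force-development and cocontraction
    metrics. Includes a motor-unit pool simulator with a shared band-limited
    oscillatory drive, an H-reflex sweep simulator and a torque-trial
    simulator for validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
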