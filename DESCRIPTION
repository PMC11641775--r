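Package: circaplast
Title: Circadian Wheel-Running Rhythm Analysis and Synaptic Puncta Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two-stage analysis of circadian synaptic plasticity
    experiments: extraction of daily/circadian locomotor rhythm parameters
    (chi-square and Fourier periodograms, rhythm robustness, activity onsets,
    activity-phase duration, onset drift, day/night activity splits, mid-activity
    breaks) from binned wheel-running records under light-dark and constant
    lighting regimes, and quantification of synaptic protein immunopuncta,
    object-based presynaptic/postsynaptic colocalization, excitatory synapse
    density, and expression-change classification from two-channel fluorescence
    fields. Includes synthetic-data generators with known ground truth for both
    data types, distribution-gated group statistics (ANOVA/Tukey or
    Kruskal-Wallis/Dunn), and an end-to-end study pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
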