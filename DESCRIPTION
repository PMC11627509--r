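Package: shepadapt
Title: Adaptation and Decoding of Shepard-Tone Context in Auditory Cortex Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how contextual Shepard-tone sequences shape the
    cortical representation of ambiguous tritone pairs. Generates Shepard-tone
    stimuli (biased pair and biased tuning paradigms), simulates adapting
    neural populations with von Mises tuning and a dynamic synaptic-depression
    model with optional direction-selective cells, and provides population
    decoders (PCA pitch-circle and complex-domain population vector), reverse
    correlation estimation of Shepard spectrotemporal receptive fields,
    directionality indices, a directional percept decoder, and adaptation
    time-course analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
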