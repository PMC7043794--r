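Package: transamp
Title: Transient Amplification Analysis and Design for Linear Recurrent Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis and design toolkit for transient amplification in linear
    recurrent rate networks r' = -r + Jr. Classifies any connectivity matrix by
    its amplification regime through the spectrum of its symmetric part,
    extracts amplified input directions and their transient readouts from the
    singular value decomposition of the propagator exp(t(J - I)), evaluates
    closed-form results for two-population, excitatory-inhibitory, random
    Gaussian and low-rank connectivities, constructs low-rank networks that
    encode specified input-to-readout transient channels, and quantifies their
    robustness to connectivity noise, input noise and multi-pattern cross-talk,
    including the storage capacity of the connectivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
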