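Package: resotone
Title: Resonance Spectra, the Harmonic Operator, and Tonal Perception Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Represents signals and musical percepts as resonance spectra,
    finite sums of complex damped oscillators (Lorentzian peaks in the
    frequency domain), and equips them with a closed-form Hilbert-space
    inner product, norm, and cosine similarity/distance. A harmonic
    operator maps a spectrum to its attenuated overtone series, giving
    models of key affinity (how well a pitch fits a key) and inter-key or
    inter-chord distance that can be fitted to probe-tone profile data by
    correlation. Includes translation between the resonance basis and the
    Fourier basis, a unitary DFT comparison, and a linear-dynamical-system
    synthesizer whose eigenmode decomposition yields exact resonance
    representations of simulated observations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
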