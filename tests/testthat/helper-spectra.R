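# Random small spectra for property-style tests. Decays are bounded away
# from zero (|gamma| in [0.01, 2]) and frequencies limited to |phi| <= 50,
# the regime the closed-form/quadrature agreement contract covers.
random_spectrum <- function(K = sample(1:5, 1), decay_sign = 1,
                            freq_range = c(-50, 50)) {
  spectrum_from_params(
    amp_mag = runif(K, 0.2, 2),
    phase = runif(K, -pi, pi),
    freq = runif(K, freq_range[1], freq_range[2]),
    decay = decay_sign * runif(K, 0.01, 2)
  )
}

single <- function(amp = 1, phase = 0, freq = 1, decay = 0.5)
  resonance_spectrum(resonance(amp, phase, freq, decay))

# the worked single-resonance example used throughout: |d| = 2, psi = 0,
# phi = 10, gamma = -1
example_resonance_spectrum <- function() single(2, 0, 10, -1)

rel_err <- function(a, b) Mod(a - b) / max(Mod(b), .Machine$double.eps)
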