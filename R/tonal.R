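#' Frequency of a semitone offset
#'
#' Equal-tempered tuning: \code{tonic_freq * 2^(offset/12)}. Offsets may be
#' negative; offset 12 doubles the frequency (the octave).
#'
#' @param offset Integer semitone offset from the tonic (vectorized).
#' @param tonic_freq Positive tonic frequency (model units; the tonal fits
#'   use 1).
#' @return Numeric vector of frequencies.
#' @export
semitone_frequency <- function(offset, tonic_freq = 1) {
  stopifnot(is.numeric(offset), all(offset == round(offset)),
            is.numeric(tonic_freq), all(tonic_freq > 0))
  tonic_freq * 2^(offset / 12)
}

#' Key (triad) model specification
#'
#' A key is modelled by its tonic triad: three resonances at the
#' fundamental frequencies of the triad tones, amplitudes
#' \eqn{(1, |d_2|, |d_3|)}, all phases zero, and one shared decay
#' \eqn{\gamma_0 > 0} that sets the spectral peak width. The tonic
#' amplitude is fixed at 1 so the model has three free parameters
#' (\eqn{\gamma_0, |d_2|, |d_3|}).
#'
#' @param quality \code{"major"} (offsets 0, 4, 7) or \code{"minor"}
#'   (offsets 0, 3, 7).
#' @param tonic_freq Positive tonic frequency \eqn{\phi_1} (default 1).
#' @param d2,d3 Relative amplitudes of the third and fifth, in [0, 1].
#' @param gamma0 Positive shared decay.
#' @param tuning \code{"equal_tempered"} (default; used by all fits) or
#'   \code{"just"} (frequency ratios 4:5:6 major, 10:12:15 minor), offered
#'   for exploration.
#' @return An object of class \code{"triad_spec"}.
#' @export
triad_spec <- function(quality = c("major", "minor"), tonic_freq = 1,
                       d2 = 1, d3 = 1, gamma0 = 0.03,
                       tuning = c("equal_tempered", "just")) {
  quality <- match.arg(quality)
  tuning <- match.arg(tuning)
  stopifnot(is.numeric(tonic_freq), length(tonic_freq) == 1L, tonic_freq > 0,
            is.numeric(d2), length(d2) == 1L, d2 >= 0, d2 <= 1,
            is.numeric(d3), length(d3) == 1L, d3 >= 0, d3 <= 1,
            is.numeric(gamma0), length(gamma0) == 1L, gamma0 > 0)
  structure(list(quality = quality, tonic_freq = tonic_freq,
                 d2 = d2, d3 = d3, gamma0 = gamma0, tuning = tuning),
            class = "triad_spec")
}

#' Resonance spectrum of a key triad
#'
#' Three resonances at the triad's fundamental frequencies (no overtones;
#' harmonic content is added explicitly by \code{\link{apply_harmonic}}),
#' amplitudes (1, d2, d3), phases 0, shared positive decay gamma0.
#'
#' @param spec A \code{\link{triad_spec}}.
#' @return A \code{\link{resonance_spectrum}} of length 3.
#' @export
triad_spectrum <- function(spec) {
  stopifnot(inherits(spec, "triad_spec"))
  freqs <- if (spec$tuning == "equal_tempered") {
    offs <- if (spec$quality == "major") c(0L, 4L, 7L) else c(0L, 3L, 7L)
    semitone_frequency(offs, spec$tonic_freq)
  } else {
    ratios <- if (spec$quality == "major") c(1, 5 / 4, 3 / 2) else c(1, 6 / 5, 3 / 2)
    spec$tonic_freq * ratios
  }
  spectrum_from_params(c(1, spec$d2, spec$d3), c(0, 0, 0), freqs,
                       rep(spec$gamma0, 3),
                       label = paste(spec$quality, "triad"))
}

#' Resonance spectrum of a single pitch
#'
#' One resonance at the pitch's fundamental frequency: amplitude 1, phase
#' 0, positive decay.
#'
#' @param freq Positive fundamental frequency.
#' @param gamma0 Positive decay (the key-affinity model shares the key's
#'   gamma0 with the probe pitch).
#' @return A \code{\link{resonance_spectrum}} of length 1.
#' @export
pitch_spectrum <- function(freq, gamma0) {
  stopifnot(freq > 0, gamma0 > 0)
  resonance_spectrum(resonance(1, 0, freq, gamma0), label = "pitch")
}

#' Key affinity of a pitch
#'
#' How well a pitch fits a key: the cosine similarity
#' \eqn{s_c(Hf, Hg)} between the harmonic spectrum of the key's tonic
#' triad and the harmonic spectrum of the probe pitch. Triad tones score
#' high (their overtones align with the triad's); the tritone scores low.
#' The probe pitch reuses the key's gamma0.
#'
#' @param key A \code{\link{triad_spec}}.
#' @param pitch_freq Positive probe frequency.
#' @param h A \code{\link{harmonic_spec}}.
#' @return Real scalar in \eqn{[-1, 1]}.
#' @export
key_affinity <- function(key, pitch_freq, h = harmonic_spec()) {
  harmonic_cosine_similarity(triad_spectrum(key),
                             pitch_spectrum(pitch_freq, key$gamma0), h)
}

#' A 12-element tonal profile
#'
#' @param values Numeric vector of exactly 12 finite values indexed by
#'   semitone offset 0-11 from the reference tonic.
#' @param kind \code{"affinity"} (values in [-1, 1]) or \code{"distance"}
#'   (values in [0, 2]). Fixture profiles on other scales (e.g. probe-tone
#'   ratings) use kind \code{"rating"}, which is unconstrained.
#' @return An object of class \code{"tonal_profile"}.
#' @export
tonal_profile <- function(values, kind = c("affinity", "distance", "rating")) {
  kind <- match.arg(kind)
  if (length(values) != 12L)
    stop("a tonal profile has exactly 12 entries, got ", length(values))
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("tonal profile values must be finite numbers")
  eps <- 1e-9
  if (kind == "affinity" && any(values < -1 - eps | values > 1 + eps))
    stop("affinity profile values must lie in [-1, 1]")
  if (kind == "distance" && any(values < -eps | values > 2 + eps))
    stop("distance profile values must lie in [0, 2]")
  structure(list(values = as.numeric(values), kind = kind),
            class = "tonal_profile")
}

#' Key-affinity profile over the 12 semitones
#'
#' Affinity of the key for probe pitches at semitone offsets 0-11 above
#' the tonic.
#'
#' @param key A \code{\link{triad_spec}}.
#' @param h A \code{\link{harmonic_spec}}.
#' @return A \code{\link{tonal_profile}} of kind \code{"affinity"}.
#' @export
affinity_profile <- function(key, h = harmonic_spec()) {
  vals <- vapply(0:11, function(o)
    key_affinity(key, semitone_frequency(o, key$tonic_freq), h), numeric(1))
  tonal_profile(vals, "affinity")
}

#' Continuous key-affinity sweep over one octave
#'
#' Affinity of the key for probe frequencies on a geometric grid from the
#' tonic to its octave (uniform in log-frequency, so semitones are equally
#' spaced on the axis). Peaks near the triad tones have nonzero width
#' controlled by gamma0, which is why nearby tunings (equal temperament vs
#' just intonation) both register as high-affinity.
#'
#' @param key A \code{\link{triad_spec}}.
#' @param h A \code{\link{harmonic_spec}}.
#' @param n_points Number of grid points >= 2 (default 1200: 1-cent steps).
#' @return A data.frame with columns \code{freq} and \code{affinity}.
#' @export
affinity_sweep <- function(key, h = harmonic_spec(), n_points = 1200) {
  stopifnot(n_points >= 2, n_points == round(n_points))
  freqs <- key$tonic_freq * 2^(seq(0, 1, length.out = n_points))
  aff <- vapply(freqs, function(fr) key_affinity(key, fr, h), numeric(1))
  data.frame(freq = freqs, affinity = aff)
}

#' The Fig-4a-style illustrative sweep preset
#'
#' Named preset for the illustrative sweep parameterization: 1/n
#' attenuation, gamma0 = 0.01, N = 50 overtones.
#'
#' @return A list with elements \code{key} (C-major-style
#'   \code{\link{triad_spec}} at tonic 1) and \code{h}
#'   (\code{\link{harmonic_spec}}).
#' @export
illustrative_sweep_preset <- function() {
  list(key = triad_spec("major", tonic_freq = 1, d2 = 1, d3 = 1, gamma0 = 0.01),
       h = harmonic_spec(50, attenuation_spec("power_law", alpha = 1, beta = 0)))
}

#' Distance between two keys
#'
#' Cosine distance between the harmonic spectra of the two tonic triads:
#' \eqn{d_c(Hf, Hg) = 1 - s_c(Hf, Hg)}. Symmetric; zero iff the harmonic
#' spectra coincide.
#'
#' @param a,b \code{\link{triad_spec}} objects.
#' @param h A \code{\link{harmonic_spec}}.
#' @return Real scalar in \eqn{[0, 2]}.
#' @export
inter_key_distance <- function(a, b, h = harmonic_spec()) {
  harmonic_cosine_distance(triad_spectrum(a), triad_spectrum(b), h)
}

#' Inter-key distance profiles from major and minor references
#'
#' Distances from a C-style major reference and minor reference (built
#' from the supplied parameters) to the 12 major and 12 minor keys at
#' semitone offsets 0-11, i.e. the four panels major-major, major-minor,
#' minor-major, minor-minor.
#'
#' @param reference A \code{\link{triad_spec}}; its tonic frequency and
#'   parameters (d2, d3, gamma0, tuning) are shared by all 24 keys. Both
#'   the major and the minor reference are built from these parameters
#'   (the \code{quality} field selects which two panels come first:
#'   the reference quality's panels are ordered reference-to-major then
#'   reference-to-minor).
#' @param h A \code{\link{harmonic_spec}}.
#' @return A named list of four \code{\link{tonal_profile}}s of kind
#'   \code{"distance"}: \code{major_major}, \code{major_minor},
#'   \code{minor_major}, \code{minor_minor}.
#' @export
distance_profile_set <- function(reference, h = harmonic_spec()) {
  stopifnot(inherits(reference, "triad_spec"))
  mk <- function(q, off) triad_spec(q,
    tonic_freq = semitone_frequency(off, reference$tonic_freq),
    d2 = reference$d2, d3 = reference$d3, gamma0 = reference$gamma0,
    tuning = reference$tuning)
  ref_major <- mk("major", 0L)
  ref_minor <- mk("minor", 0L)
  one <- function(ref, q) tonal_profile(vapply(0:11, function(o)
    inter_key_distance(ref, mk(q, o), h), numeric(1)), "distance")
  list(major_major = one(ref_major, "major"),
       major_minor = one(ref_major, "minor"),
       minor_major = one(ref_minor, "major"),
       minor_minor = one(ref_minor, "minor"))
}

#' Full 24 x 24 inter-key distance matrix
#'
#' Distances between all 24 keys: majors C..B by ascending semitone, then
#' minors C..B (row and column order).
#'
#' @param params A \code{\link{triad_spec}} providing the shared
#'   parameters (tonic frequency of C, d2, d3, gamma0, tuning).
#' @param h A \code{\link{harmonic_spec}}.
#' @return A symmetric 24 x 24 numeric matrix with zero diagonal and
#'   dimnames like \code{"M0"}..\code{"M11"}, \code{"m0"}..\code{"m11"}.
#' @export
inter_key_distance_matrix <- function(params, h = harmonic_spec()) {
  stopifnot(inherits(params, "triad_spec"))
  keys <- c(lapply(0:11, function(o) triad_spec("major",
              tonic_freq = semitone_frequency(o, params$tonic_freq),
              d2 = params$d2, d3 = params$d3, gamma0 = params$gamma0,
              tuning = params$tuning)),
            lapply(0:11, function(o) triad_spec("minor",
              tonic_freq = semitone_frequency(o, params$tonic_freq),
              d2 = params$d2, d3 = params$d3, gamma0 = params$gamma0,
              tuning = params$tuning)))
  n <- length(keys)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) m[i, j] <- inter_key_distance(keys[[i]], keys[[j]], h)
    if (j < i) m[i, j] <- m[j, i]
  }
  dimnames(m) <- list(c(paste0("M", 0:11), paste0("m", 0:11)),
                      c(paste0("M", 0:11), paste0("m", 0:11)))
  m
}
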