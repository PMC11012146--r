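#' Construct a single resonance
#'
#' A resonance is a complex damped (or driven) oscillator
#' \deqn{|d| e^{i\psi} e^{-i(\phi + i\gamma)t},}
#' equivalently a Lorentzian peak in the frequency domain. It is the
#' primitive of the spectral representation used throughout this package.
#'
#' @param amp_mag Non-negative real; modulus of the complex amplitude
#'   \eqn{|d|}. Initial amplitude of the oscillator in the time domain.
#' @param phase Real; argument \eqn{\psi} of the complex amplitude, radians.
#' @param freq Real; centre frequency \eqn{\phi} (radians per unit time in
#'   the model's dimensionless units).
#' @param decay Nonzero real; decay \eqn{\gamma}. Under the convention
#'   \eqn{e^{-i(\phi+i\gamma)t}}, \code{decay < 0} decays forward in time
#'   and \code{decay > 0} grows; the tonal models use \code{decay > 0}.
#'   \code{decay == 0} is rejected: an undamped oscillator is not
#'   square-integrable over the whole frequency axis.
#' @return An object of class \code{"resonance"}: a list with fields
#'   \code{amp_mag}, \code{phase}, \code{freq}, \code{decay}.
#' @examples
#' r <- resonance(amp_mag = 2, phase = 0, freq = 10, decay = -1)
#' @export
resonance <- function(amp_mag, phase = 0, freq, decay) {
  stopifnot(is.numeric(amp_mag), length(amp_mag) == 1L, is.finite(amp_mag),
            is.numeric(phase),   length(phase)   == 1L, is.finite(phase),
            is.numeric(freq),    length(freq)    == 1L, is.finite(freq),
            is.numeric(decay),   length(decay)   == 1L, is.finite(decay))
  if (amp_mag < 0) stop("'amp_mag' must be non-negative")
  if (decay == 0) stop("'decay' must be nonzero: gamma = 0 is not square-integrable")
  structure(list(amp_mag = amp_mag, phase = phase, freq = freq, decay = decay),
            class = "resonance")
}

#' Construct a resonance spectrum
#'
#' A resonance spectrum is a finite ordered collection of resonances; it is
#' the object all inner products act on. In the frequency domain it is
#' \deqn{f(\phi) = \frac{i}{\sqrt{2\pi}} \sum_k \frac{d_k}{\phi - \omega_k}}
#' with complex amplitudes \eqn{d_k = |d_k| e^{i\psi_k}} and complex
#' frequencies \eqn{\omega_k = \phi_k + i\gamma_k}.
#'
#' @param resonances List of \code{\link{resonance}} objects, length >= 1.
#' @param label Optional free-text label.
#' @return An object of class \code{"resonance_spectrum"}.
#' @examples
#' f <- resonance_spectrum(list(resonance(2, 0, 10, -1)), label = "example")
#' @export
resonance_spectrum <- function(resonances, label = "") {
  if (inherits(resonances, "resonance")) resonances <- list(resonances)
  if (!is.list(resonances) || length(resonances) < 1L)
    stop("'resonances' must be a non-empty list of resonance objects")
  ok <- vapply(resonances, inherits, logical(1), what = "resonance")
  if (!all(ok)) stop("all elements of 'resonances' must be resonance objects")
  structure(list(resonances = resonances, label = as.character(label)[1L]),
            class = "resonance_spectrum")
}

#' @export
print.resonance_spectrum <- function(x, ...) {
  cat(sprintf("Resonance spectrum%s: %d resonance(s)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$resonances)))
  p <- spectrum_params(x)
  print(data.frame(amp_mag = p$amp_mag, phase = p$phase,
                   freq = p$freq, decay = p$decay))
  invisible(x)
}

#' @export
length.resonance_spectrum <- function(x) length(x$resonances)

# Extract parameter vectors (amp_mag, phase, freq, decay, complex amplitude d)
# from a spectrum; all closed-form algebra is vectorized over these.
spectrum_params <- function(f) {
  stopifnot(inherits(f, "resonance_spectrum"))
  list(
    amp_mag = vapply(f$resonances, `[[`, numeric(1), "amp_mag"),
    phase   = vapply(f$resonances, `[[`, numeric(1), "phase"),
    freq    = vapply(f$resonances, `[[`, numeric(1), "freq"),
    decay   = vapply(f$resonances, `[[`, numeric(1), "decay")
  )
}

# complex amplitudes d_k = |d_k| e^{i psi_k}
complex_amps <- function(p) p$amp_mag * exp(1i * p$phase)

#' Build a spectrum from parameter vectors
#'
#' Vectorized convenience constructor: one resonance per element.
#'
#' @param amp_mag,phase,freq,decay Equal-length numeric vectors.
#' @param label Optional label.
#' @return A \code{\link{resonance_spectrum}}.
#' @export
spectrum_from_params <- function(amp_mag, phase, freq, decay, label = "") {
  n <- length(amp_mag)
  stopifnot(length(phase) == n, length(freq) == n, length(decay) == n, n >= 1L)
  resonance_spectrum(lapply(seq_len(n), function(k)
    resonance(amp_mag[k], phase[k], freq[k], decay[k])), label = label)
}

#' Concatenate resonance spectra
#'
#' The sum of the underlying signals: the resonances of all arguments in
#' order. Used to express linearity of the harmonic operator.
#'
#' @param ... Resonance spectra.
#' @param label Optional label for the result.
#' @return A \code{\link{resonance_spectrum}}.
#' @export
concat_spectra <- function(..., label = "") {
  parts <- list(...)
  stopifnot(length(parts) >= 1L)
  resonance_spectrum(unlist(lapply(parts, function(f) {
    stopifnot(inherits(f, "resonance_spectrum"))
    f$resonances
  }), recursive = FALSE), label = label)
}

#' Scale the amplitudes of a spectrum
#'
#' @param f A resonance spectrum.
#' @param c Positive real scale factor.
#' @return The spectrum with every amplitude multiplied by \code{c}.
#' @export
scale_spectrum <- function(f, c) {
  stopifnot(inherits(f, "resonance_spectrum"), is.numeric(c), length(c) == 1L, c >= 0)
  p <- spectrum_params(f)
  spectrum_from_params(p$amp_mag * c, p$phase, p$freq, p$decay, label = f$label)
}

#' Evaluate a spectrum in the time domain
#'
#' Computes the signal
#' \deqn{x(t) = \sum_k |d_k| e^{i\psi_k} e^{-i(\phi_k + i\gamma_k)t}}
#' at the requested times.
#'
#' @param spectrum A \code{\link{resonance_spectrum}}.
#' @param times Numeric vector of times (may be empty).
#' @return Complex vector, one value per time.
#' @examples
#' f <- resonance_spectrum(resonance(2, 0, 10, -1))
#' eval_time(f, 0)  # 2+0i
#' @export
eval_time <- function(spectrum, times) {
  stopifnot(is.numeric(times), all(is.finite(times)))
  if (length(times) == 0L) return(complex(0))
  p <- spectrum_params(spectrum)
  d <- complex_amps(p)
  omega <- complex(real = p$freq, imaginary = p$decay)
  # K x T matrix of e^{-i omega_k t}; column sums weighted by d
  as.vector(d %*% exp(-1i * outer(omega, times)))
}

#' Evaluate a spectrum in the frequency domain
#'
#' Computes
#' \deqn{f(\phi) = \frac{i}{\sqrt{2\pi}} \sum_k \frac{d_k}{\phi - \omega_k}}
#' at the requested real frequencies. Each term is a complex Lorentzian
#' peak centred at \eqn{\phi_k} with width set by \eqn{\gamma_k}.
#'
#' @param spectrum A \code{\link{resonance_spectrum}}.
#' @param freqs Numeric vector of real frequencies.
#' @return Complex vector, one value per frequency.
#' @export
eval_freq <- function(spectrum, freqs) {
  stopifnot(is.numeric(freqs), all(is.finite(freqs)))
  if (length(freqs) == 0L) return(complex(0))
  p <- spectrum_params(spectrum)
  d <- complex_amps(p)
  omega <- complex(real = p$freq, imaginary = p$decay)
  denom <- outer(freqs, omega, `-`)     # T x K
  (1i / sqrt(2 * pi)) * as.vector(denom^-1 %*% d)
}

#' Closed-form Hilbert-space inner product of two resonance spectra
#'
#' The \eqn{L^2} inner product over the whole frequency axis has the closed
#' pairwise form
#' \deqn{\langle f|g\rangle = \sum_{j,k}
#'   \frac{i |d_j||d_k| e^{i(\psi_j-\psi_k)}}
#'        {(\phi_j-\phi_k) + i(\gamma_j+\gamma_k)} \, \mathrm{sgn}(\gamma_j)}
#' where the sum runs over pairs with \eqn{\mathrm{sgn}(\gamma_j) =
#' \mathrm{sgn}(\gamma_k)}; pairs whose decays have opposite signs
#' contribute exactly zero (such resonances are orthogonal). The second
#' argument is conjugated, so the product is Hermitian:
#' \code{inner_product(g, f) == Conj(inner_product(f, g))}.
#'
#' @param f,g Resonance spectra.
#' @return A complex scalar.
#' @examples
#' f <- resonance_spectrum(resonance(1, 0, 3, 0.5))
#' inner_product(f, f)  # 1/(2*0.5) = 1
#' @export
inner_product <- function(f, g) {
  pf <- spectrum_params(f)
  pg <- spectrum_params(g)
  if (any(pf$decay == 0) || any(pg$decay == 0))
    stop("inner_product requires nonzero decay for every resonance")
  df <- complex_amps(pf)
  dg <- complex_amps(pg)
  num <- 1i * outer(df, Conj(dg))
  den <- outer(pf$freq, pg$freq, `-`) +
    1i * outer(pf$decay, pg$decay, `+`)
  same <- outer(sign(pf$decay), sign(pg$decay), `==`)
  terms <- (num / den) * sign(pf$decay)   # sgn(gamma_j), recycled down columns
  sum(terms[same])
}

#' Norm of a resonance spectrum
#'
#' \eqn{\|f\| = \sqrt{\langle f|f\rangle}}; the squared norm is real and
#' strictly positive for any nonzero spectrum (it equals the total power
#' spectral density).
#'
#' @param f A resonance spectrum.
#' @return Non-negative real scalar.
#' @export
spectrum_norm <- function(f) {
  n2 <- Re(inner_product(f, f))
  sqrt(max(n2, 0))
}

#' Cosine similarity between two resonance spectra
#'
#' \deqn{s_c(f,g) = \mathrm{Re}[\langle f|g\rangle] / (\|f\|\,\|g\|)}
#' Lies in \eqn{[-1, 1]}, is symmetric, and is invariant under positive
#' rescaling of either spectrum's amplitudes.
#'
#' @param f,g Resonance spectra with strictly positive norms.
#' @return Real scalar in \eqn{[-1, 1]}.
#' @export
cosine_similarity <- function(f, g) {
  nf <- spectrum_norm(f)
  ng <- spectrum_norm(g)
  if (nf <= 0 || ng <= 0)
    stop("cosine_similarity is undefined for a zero-norm spectrum")
  s <- Re(inner_product(f, g)) / (nf * ng)
  # clip roundoff spill just outside [-1, 1]
  min(1, max(-1, s))
}

#' Cosine distance between two resonance spectra
#'
#' \eqn{d_c(f,g) = 1 - s_c(f,g)}; range \eqn{[0, 2]}, zero for identical
#' spectra, 1 for orthogonal spectra.
#'
#' @inheritParams cosine_similarity
#' @return Real scalar in \eqn{[0, 2]}.
#' @export
cosine_distance <- function(f, g) 1 - cosine_similarity(f, g)

#' Numerical-quadrature inner product (test oracle)
#'
#' Integrates \eqn{f(\phi)\,\overline{g(\phi)}} numerically over
#' \eqn{(-\infty, \infty)}, independently of the closed form, so the two
#' routes can be checked against each other. The finite interval
#' \code{(-halfwidth, halfwidth)} is partitioned at the resonance peak
#' frequencies (adaptive quadrature resolves narrow Lorentzians reliably
#' when each peak sits at a subinterval endpoint); the tails beyond
#' \code{halfwidth} are integrated on semi-infinite ranges.
#'
#' @param f,g Resonance spectra.
#' @param halfwidth Positive real; all peaks must lie well inside
#'   \code{(-halfwidth, halfwidth)}.
#' @param tol Requested relative tolerance per subinterval.
#' @return A complex scalar.
#' @export
quadrature_inner_product <- function(f, g, halfwidth = 1e4, tol = 1e-10) {
  stopifnot(halfwidth > 0, tol > 0)
  pf <- spectrum_params(f)
  pg <- spectrum_params(g)
  if (max(abs(c(pf$freq, pg$freq))) >= halfwidth)
    stop("'halfwidth' must exceed every peak frequency")
  integrand <- function(phi, part)
    part(eval_freq(f, phi) * Conj(eval_freq(g, phi)))
  brk <- sort(unique(c(-halfwidth, pf$freq, pg$freq, halfwidth)))
  piece <- function(lo, hi, part) {
    r <- stats::integrate(integrand, lo, hi, part = part,
                          rel.tol = tol, abs.tol = tol,
                          subdivisions = 2000L, stop.on.error = FALSE)
    if (!r$message %in% c("OK", "the integral is probably divergent"))
      stop("quadrature failed: ", r$message)
    r$value
  }
  one_part <- function(part) {
    finite <- sum(vapply(seq_len(length(brk) - 1L), function(i)
      piece(brk[i], brk[i + 1L], part), numeric(1)))
    finite + piece(halfwidth, Inf, part) + piece(-Inf, -halfwidth, part)
  }
  complex(real = one_part(Re), imaginary = one_part(Im))
}
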