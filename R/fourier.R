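#' Normalized sinc at complex argument
#'
#' \eqn{\mathrm{sinc}(z) = \sin(\pi z)/(\pi z)} with the removable
#' singularity handled by a series for \eqn{|z| < 10^{-8}}.
#'
#' @param z Complex (or numeric) vector.
#' @return Complex vector.
#' @export
csinc <- function(z) {
  z <- as.complex(z)
  out <- rep(1 + 0i, length(z))
  big <- Mod(z) >= 1e-8
  out[big] <- sin(pi * z[big]) / (pi * z[big])
  small <- !big
  out[small] <- 1 - (pi * z[small])^2 / 6
  out
}

#' Projection of a resonance onto a Fourier basis function
#'
#' On the fixed analysis interval \eqn{(-\pi, \pi)} with orthonormal basis
#' \eqn{\varphi_n(t) = e^{-int}/\sqrt{2\pi}}, the projection of the
#' resonance \eqn{e^{-i\omega t}} is
#' \deqn{\langle r|\varphi_n\rangle = \int_{-\pi}^{\pi} e^{-i\omega t}
#'   \frac{e^{int}}{\sqrt{2\pi}}\,dt = \sqrt{2\pi}\,\mathrm{sinc}(n-\omega).}
#' The second slot is conjugated (\eqn{\overline{\varphi_n} = e^{int}/
#' \sqrt{2\pi}}), the convention that makes this closed form hold. Because
#' \eqn{\omega} has nonzero imaginary part when the resonance decays, the
#' sinc never hits an integer zero: every Fourier coefficient of a damped
#' resonance is nonzero.
#'
#' @param r A \code{\link{resonance}}; its amplitude and phase are ignored
#'   (the projection is of the unit oscillator \eqn{e^{-i\omega t}}).
#' @param n Integer Fourier index (vectorized).
#' @return Complex vector.
#' @export
resonance_fourier_projection <- function(r, n) {
  stopifnot(inherits(r, "resonance") || (is.list(r) && !is.null(r$freq)))
  omega <- complex(real = r$freq, imaginary = r$decay)
  sqrt(2 * pi) * csinc(n - omega)
}

#' Fourier coefficient of a resonance spectrum
#'
#' \deqn{\langle f|\varphi_n\rangle = \sqrt{2\pi}\sum_k d_k\,
#'   \mathrm{sinc}(n - \omega_k)}
#' on \eqn{(-\pi,\pi)}: a K-term weighted sum of sinc functions. Contrast
#' with a single resonance, which needs infinitely many Fourier terms.
#'
#' @param f A \code{\link{resonance_spectrum}}.
#' @param n Integer Fourier index (vectorized).
#' @return Complex vector, one coefficient per index.
#' @export
spectrum_fourier_coefficient <- function(f, n) {
  p <- spectrum_params(f)
  d <- complex_amps(p)
  omega <- complex(real = p$freq, imaginary = p$decay)
  vapply(n, function(nn) sum(d * sqrt(2 * pi) * csinc(nn - omega)),
         complex(1))
}

#' Truncated Fourier reconstruction of a spectrum's signal
#'
#' \deqn{\sum_{n=-n_{max}}^{n_{max}} \langle f|\varphi_n\rangle
#'   \varphi_n(t)} with \eqn{\varphi_n(t) = e^{-int}/\sqrt{2\pi}};
#' converges pointwise to \code{\link{eval_time}} on \eqn{(-\pi,\pi)} as
#' \code{n_max} grows.
#'
#' @param f A \code{\link{resonance_spectrum}}.
#' @param n_max Non-negative integer truncation order.
#' @param times Numeric vector of times strictly inside \eqn{(-\pi,\pi)}.
#' @return Complex vector, one value per time.
#' @export
reconstruct_truncated <- function(f, n_max, times) {
  stopifnot(n_max >= 0, n_max == round(n_max))
  if (any(times <= -pi | times >= pi))
    stop("'times' must lie strictly inside (-pi, pi)")
  n <- seq.int(-n_max, n_max)
  coef <- spectrum_fourier_coefficient(f, n)
  basis <- exp(-1i * outer(n, times)) / sqrt(2 * pi)  # |n| x T
  as.vector(coef %*% basis)
}

#' Construct a uniformly sampled signal
#'
#' @param samples Numeric or complex vector, length >= 1.
#' @param sample_rate Positive sampling rate in Hz.
#' @return An object of class \code{"sampled_signal"}.
#' @export
sampled_signal <- function(samples, sample_rate) {
  stopifnot(length(samples) >= 1L, is.numeric(sample_rate),
            length(sample_rate) == 1L, sample_rate > 0)
  structure(list(samples = as.complex(samples), sample_rate = sample_rate),
            class = "sampled_signal")
}

#' Unitary discrete Fourier transform
#'
#' \deqn{\hat f_k = \frac{1}{\sqrt N}\sum_{n=0}^{N-1} f_n e^{i 2\pi k n/N}}
#' Note the exponent sign (+i) and the \eqn{1/\sqrt N} normalization, which
#' make the transform unitary (Parseval holds exactly); this is the
#' opposite sign and a different scale from most library defaults, so the
#' implementation adapts \code{stats::fft} accordingly.
#'
#' @param signal A \code{\link{sampled_signal}} (or plain vector, taken at
#'   sample rate 1).
#' @return A list of class \code{"fourier_coefficients"} with fields
#'   \code{indices} (0-based bin index k), \code{coefficients} (complex),
#'   and \code{frequencies_hz} (bin centres from
#'   \code{\link{dft_bin_frequencies}}).
#' @export
dft <- function(signal) {
  if (!inherits(signal, "sampled_signal")) signal <- sampled_signal(signal, 1)
  x <- signal$samples
  n <- length(x)
  coef <- stats::fft(x, inverse = TRUE) / sqrt(n)
  structure(list(indices = 0:(n - 1L),
                 coefficients = coef,
                 frequencies_hz = dft_bin_frequencies(n, signal$sample_rate)),
            class = "fourier_coefficients")
}

#' DFT bin centre frequencies
#'
#' Bin k of an N-point DFT at sampling rate fs sits at \eqn{k\,fs/N} Hz,
#' regardless of the structure of the signal; e.g. 1024 samples at 44.1 kHz
#' give bins at 0, 43.07, 86.13, ... Hz.
#'
#' @param n_samples Positive integer N.
#' @param sample_rate Positive sampling rate in Hz.
#' @return Numeric vector of N frequencies in Hz.
#' @export
dft_bin_frequencies <- function(n_samples, sample_rate) {
  stopifnot(n_samples >= 1, n_samples == round(n_samples), sample_rate > 0)
  (0:(n_samples - 1L)) * sample_rate / n_samples
}

#' Write Fourier coefficients to CSV
#'
#' Columns \code{n}, \code{re}, \code{im}.
#'
#' @param coefs A \code{"fourier_coefficients"} object, or a list with
#'   \code{indices} and \code{coefficients}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fourier_csv <- function(coefs, path) {
  utils::write.csv(data.frame(n = coefs$indices,
                              re = Re(coefs$coefficients),
                              im = Im(coefs$coefficients)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a sampled signal from a single-column CSV
#'
#' @param path CSV with one numeric column (header optional but
#'   recommended).
#' @param sample_rate Sampling rate in Hz.
#' @return A \code{\link{sampled_signal}}.
#' @export
read_signal_csv <- function(path, sample_rate) {
  x <- utils::read.csv(path)
  if (ncol(x) != 1L) stop("expected a single-column CSV: ", path)
  sampled_signal(x[[1L]], sample_rate)
}
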