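#' Attenuation specification for the harmonic operator
#'
#' Per-overtone amplitude weight \eqn{A(\phi, n)}. Families:
#' \describe{
#'   \item{\code{constant}}{\eqn{A = c}; the best-fit attenuation of the
#'     tonal models is effectively constant, so this is the default used
#'     there (with \eqn{c = 1}).}
#'   \item{\code{power_law}}{\eqn{A(n) = 1/(n^\alpha + \beta)}, with
#'     \eqn{\alpha > 0} the attenuation rate and \eqn{\beta} a flattening
#'     offset; \eqn{\alpha = 1, \beta = 0} gives the classic \eqn{1/n}
#'     overtone rolloff.}
#'   \item{\code{one_over_f}}{\eqn{A = 1/\phi} evaluated at the overtone's
#'     centre frequency (1/f-noise-like rolloff); the only
#'     frequency-dependent family.}
#'   \item{\code{table}}{explicit per-overtone weights.}
#' }
#'
#' @param family One of \code{"constant"}, \code{"power_law"},
#'   \code{"one_over_f"}, \code{"table"}.
#' @param alpha,beta Power-law parameters (power_law only); requires
#'   \eqn{n^\alpha + \beta > 0} for every n in use.
#' @param constant_value Positive weight (constant only).
#' @param table Numeric vector of per-overtone weights (table only).
#' @return An object of class \code{"attenuation_spec"}.
#' @export
attenuation_spec <- function(family = c("constant", "power_law", "one_over_f", "table"),
                             alpha = NULL, beta = NULL,
                             constant_value = 1, table = NULL) {
  family <- match.arg(family)
  spec <- switch(family,
    constant = {
      stopifnot(is.numeric(constant_value), length(constant_value) == 1L,
                constant_value > 0)
      list(family = family, constant_value = constant_value)
    },
    power_law = {
      stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0,
                is.numeric(beta), length(beta) == 1L, is.finite(beta))
      list(family = family, alpha = alpha, beta = beta)
    },
    one_over_f = list(family = family),
    table = {
      stopifnot(is.numeric(table), length(table) >= 1L, all(table > 0))
      list(family = family, table = table)
    })
  structure(spec, class = "attenuation_spec")
}

#' Harmonic expansion specification
#'
#' The overtone count N together with the attenuation function applied to
#' each overtone's amplitude. N is always finite; the tonal models of this
#' package fix N = 12.
#'
#' @param n_overtones Positive integer N (at most \code{cap}).
#' @param attenuation An \code{\link{attenuation_spec}}; default constant 1
#'   (flat), the form the fitted tonal models use.
#' @param cap Upper bound on N (default 256), a guard against runaway
#'   expansions.
#' @return An object of class \code{"harmonic_spec"}.
#' @export
harmonic_spec <- function(n_overtones = 12,
                          attenuation = attenuation_spec("constant"),
                          cap = 256L) {
  stopifnot(is.numeric(n_overtones), length(n_overtones) == 1L,
            n_overtones >= 1, n_overtones == round(n_overtones),
            n_overtones <= cap,
            inherits(attenuation, "attenuation_spec"))
  structure(list(n_overtones = as.integer(n_overtones),
                 attenuation = attenuation),
            class = "harmonic_spec")
}

#' Evaluate an attenuation weight
#'
#' @param spec An \code{\link{attenuation_spec}}.
#' @param n Positive integer overtone number (vectorized).
#' @param overtone_freq Centre frequency of the overtone (used by the
#'   \code{one_over_f} family only; vectorized with \code{n}).
#' @return Positive numeric vector of weights.
#' @export
attenuation_weight <- function(spec, n, overtone_freq = NULL) {
  stopifnot(inherits(spec, "attenuation_spec"), all(n >= 1), all(n == round(n)))
  switch(spec$family,
    constant = rep(spec$constant_value, length(n)),
    power_law = {
      w <- n^spec$alpha + spec$beta
      if (any(w <= 0))
        stop("power_law attenuation requires n^alpha + beta > 0 for all n in use")
      1 / w
    },
    one_over_f = {
      if (is.null(overtone_freq))
        stop("one_over_f attenuation needs the overtone frequency")
      if (any(overtone_freq <= 0))
        stop("one_over_f attenuation requires positive overtone frequencies")
      1 / overtone_freq
    },
    table = {
      if (max(n) > length(spec$table))
        stop("attenuation table shorter than requested overtone number")
      spec$table[n]
    })
}

#' Apply the harmonic operator
#'
#' Maps a resonance spectrum to its harmonic spectrum: each of the K seed
#' resonances is replaced by N overtones, the (k, n) member having
#' frequency \eqn{n\phi_k}, phase \eqn{n\psi_k}, the seed's decay
#' \eqn{\gamma_k}, and amplitude \eqn{A(n\phi_k, n)\,|d_k|}. H is linear:
#' it commutes with amplitude scaling and spectrum concatenation.
#'
#' @param f A \code{\link{resonance_spectrum}}.
#' @param spec A \code{\link{harmonic_spec}}.
#' @return A \code{\link{resonance_spectrum}} with K*N resonances, ordered
#'   seed-major (all overtones of seed 1, then seed 2, ...).
#' @examples
#' f <- resonance_spectrum(resonance(2, 0, 10, -1))
#' Hf <- apply_harmonic(f, harmonic_spec(3, attenuation_spec("power_law",
#'                                                           alpha = 1, beta = 0)))
#' @export
apply_harmonic <- function(f, spec) {
  stopifnot(inherits(spec, "harmonic_spec"))
  p <- spectrum_params(f)
  N <- spec$n_overtones
  n <- rep(seq_len(N), times = length(p$freq))      # overtone number
  kk <- rep(seq_along(p$freq), each = N)            # seed index
  freq <- n * p$freq[kk]
  amp <- attenuation_weight(spec$attenuation, n, overtone_freq = freq) *
    p$amp_mag[kk]
  spectrum_from_params(amp, n * p$phase[kk], freq, p$decay[kk],
                       label = f$label)
}

# Pairwise closed-form sum shared by the specialized harmonic inner
# products: sum over all (row, col) pairs of
#   i * d_row * conj(d_col) / ((freq_row - freq_col) + i(dec_row + dec_col))
# with the opposite-decay-sign orthogonality rule.
pairwise_ip_sum <- function(d_row, freq_row, dec_row, d_col, freq_col, dec_col) {
  num <- 1i * outer(d_row, Conj(d_col))
  den <- outer(freq_row, freq_col, `-`) + 1i * outer(dec_row, dec_col, `+`)
  same <- outer(sign(dec_row), sign(dec_col), `==`)
  terms <- (num / den) * sign(dec_row)
  sum(terms[same])
}

#' Inner product of a spectrum with a harmonic spectrum
#'
#' \eqn{\langle f|Hg\rangle}: how much the power of \code{f} coincides with
#' the overtone structure of \code{g} (relative harmonicity). Computed by
#' the specialized triple sum over (n, j, k) of pairwise closed-form terms
#' with \code{g}'s overtones attenuated; it equals
#' \code{inner_product(f, apply_harmonic(g, spec))} exactly, and the two
#' routes are used as mutual consistency oracles in the tests.
#'
#' @param f,g Resonance spectra.
#' @param spec A \code{\link{harmonic_spec}} applied to \code{g}.
#' @return A complex scalar.
#' @export
inner_product_with_harmonic <- function(f, g, spec) {
  stopifnot(inherits(spec, "harmonic_spec"))
  pf <- spectrum_params(f)
  pg <- spectrum_params(g)
  if (any(pf$decay == 0) || any(pg$decay == 0))
    stop("inner products require nonzero decay for every resonance")
  df <- complex_amps(pf)
  dg <- complex_amps(pg)
  N <- spec$n_overtones
  total <- 0 + 0i
  for (n in seq_len(N)) {
    An <- attenuation_weight(spec$attenuation, rep(n, length(pg$freq)),
                             overtone_freq = n * pg$freq)
    total <- total + pairwise_ip_sum(
      df, pf$freq, pf$decay,
      An * pg$amp_mag * exp(1i * n * pg$phase), n * pg$freq, pg$decay)
  }
  total
}

#' Inner product of two harmonic spectra
#'
#' \eqn{\langle Hf|Hg\rangle}: overlap of two overtone series. When the
#' dominant frequency of one spectrum is an overtone of the other's, the
#' higher overtones align too and the product is large. Computed by the
#' specialized quadruple sum over (n, m, j, k); equals
#' \code{inner_product(apply_harmonic(f, spec), apply_harmonic(g, spec))}
#' and is Hermitian in (f, g).
#'
#' @param f,g Resonance spectra.
#' @param spec A \code{\link{harmonic_spec}} applied to both.
#' @return A complex scalar.
#' @export
harmonic_harmonic_inner_product <- function(f, g, spec) {
  stopifnot(inherits(spec, "harmonic_spec"))
  pf <- spectrum_params(f)
  pg <- spectrum_params(g)
  if (any(pf$decay == 0) || any(pg$decay == 0))
    stop("inner products require nonzero decay for every resonance")
  N <- spec$n_overtones
  total <- 0 + 0i
  for (n in seq_len(N)) {
    An <- attenuation_weight(spec$attenuation, rep(n, length(pf$freq)),
                             overtone_freq = n * pf$freq)
    dfn <- An * pf$amp_mag * exp(1i * n * pf$phase)
    for (m in seq_len(N)) {
      Am <- attenuation_weight(spec$attenuation, rep(m, length(pg$freq)),
                               overtone_freq = m * pg$freq)
      total <- total + pairwise_ip_sum(
        dfn, n * pf$freq, pf$decay,
        Am * pg$amp_mag * exp(1i * m * pg$phase), m * pg$freq, pg$decay)
    }
  }
  total
}

#' Cosine similarity between harmonic spectra
#'
#' \eqn{s_c(Hf, Hg)}: the cosine similarity of the two overtone-expanded
#' spectra. Since Hf is itself a resonance spectrum this inherits all the
#' inner-product invariants (range, symmetry, amplitude-scale invariance).
#'
#' @param f,g Resonance spectra.
#' @param spec A \code{\link{harmonic_spec}}.
#' @return Real scalar in \eqn{[-1, 1]}.
#' @export
harmonic_cosine_similarity <- function(f, g, spec) {
  cosine_similarity(apply_harmonic(f, spec), apply_harmonic(g, spec))
}

#' Cosine distance between harmonic spectra
#'
#' \eqn{1 - s_c(Hf, Hg)}.
#'
#' @inheritParams harmonic_cosine_similarity
#' @return Real scalar in \eqn{[0, 2]}.
#' @export
harmonic_cosine_distance <- function(f, g, spec) {
  1 - harmonic_cosine_similarity(f, g, spec)
}
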