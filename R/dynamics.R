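#' Linear dynamical system specification
#'
#' A damped linear system \eqn{x' = Ax} with \eqn{A = U \Lambda U^*}
#' (spectral theorem: unitary modal basis U, diagonal eigenvalues), an
#' observation functional \eqn{y = b^* x}, and an initial state. The
#' observation \eqn{y(t) = \sum_k e^{\lambda_k t}\, b^* P_k x(0)} is
#' exactly a resonance spectrum with \eqn{\omega_k = i\lambda_k} and
#' \eqn{d_k = b^* P_k x(0)}; this module is the package's synthetic-data
#' generator and the demonstration of that equivalence.
#'
#' @param eigenvalues Complex vector of K eigenvalues; for a damped system
#'   every real part must be negative.
#' @param modal_basis K x K complex matrix, unitary to 1e-10.
#' @param observation Complex K-vector b (the observation is b* x).
#' @param initial_state Complex K-vector x(0).
#' @param seed Integer seed recorded with the spec (for provenance).
#' @param damped Logical; if TRUE (default) enforce Re(lambda) < 0.
#' @return An object of class \code{"linear_system_spec"}.
#' @export
linear_system_spec <- function(eigenvalues, modal_basis, observation,
                               initial_state, seed = NA_integer_,
                               damped = TRUE) {
  K <- length(eigenvalues)
  eigenvalues <- as.complex(eigenvalues)
  modal_basis <- as.matrix(modal_basis)
  stopifnot(K >= 1, all(dim(modal_basis) == c(K, K)),
            length(observation) == K, length(initial_state) == K)
  uerr <- max(Mod(modal_basis %*% Conj(t(modal_basis)) - diag(K)))
  if (uerr > 1e-10)
    stop(sprintf("modal_basis is not unitary (max |UU* - I| = %.2e)", uerr))
  if (damped && any(Re(eigenvalues) >= 0))
    stop("a damped system requires Re(lambda) < 0 for every eigenvalue")
  structure(list(dimension = K, eigenvalues = eigenvalues,
                 modal_basis = modal_basis,
                 observation = as.complex(observation),
                 initial_state = as.complex(initial_state),
                 seed = as.integer(seed), damped = damped),
            class = "linear_system_spec")
}

#' Draw a random damped linear system
#'
#' Seeded generator: eigenvalues with real parts uniform in [-2, -0.01]
#' and imaginary parts uniform in [-50, 50]; a Haar-ish random unitary
#' modal basis (QR of a complex Gaussian matrix with phase-fixed
#' diagonal); complex Gaussian observation vector and initial state.
#' Reproducible per seed.
#'
#' @param dimension Positive integer K.
#' @param seed Integer seed.
#' @return A \code{\link{linear_system_spec}}.
#' @export
random_system <- function(dimension, seed) {
  stopifnot(dimension >= 1, dimension == round(dimension))
  set.seed(seed)
  K <- as.integer(dimension)
  lambda <- complex(real = stats::runif(K, -2, -0.01),
                    imaginary = stats::runif(K, -50, 50))
  Z <- matrix(complex(real = stats::rnorm(K * K),
                      imaginary = stats::rnorm(K * K)), K, K)
  qrz <- qr(Z)
  U <- qr.Q(qrz)
  dR <- diag(qr.R(qrz))
  # fix column phases so the draw is a well-defined function of the seed
  U <- U %*% diag(Conj(dR) / Mod(dR), K, K)
  b <- complex(real = stats::rnorm(K), imaginary = stats::rnorm(K))
  x0 <- complex(real = stats::rnorm(K), imaginary = stats::rnorm(K))
  linear_system_spec(lambda, U, b, x0, seed = seed, damped = TRUE)
}

#' Simulate the observation of a linear system
#'
#' \eqn{y(t) = b^* e^{At} x(0)} computed through the modal decomposition
#' \eqn{y(t) = \sum_k e^{\lambda_k t}\, b^* P_k x(0)} with projectors
#' \eqn{P_k = u_k u_k^*}.
#'
#' @param sys A \code{\link{linear_system_spec}}.
#' @param times Numeric vector of times >= 0.
#' @return Complex vector of observations, one per time.
#' @export
simulate_observation <- function(sys, times) {
  stopifnot(inherits(sys, "linear_system_spec"), all(times >= 0))
  if (length(times) == 0L) return(complex(0))
  amps <- modal_amplitudes(sys)
  as.vector(amps %*% exp(outer(sys$eigenvalues, times)))
}

# b* P_k x(0) for every mode k
modal_amplitudes <- function(sys) {
  U <- sys$modal_basis
  # b* u_k  and  u_k* x0, combined: (b* u_k)(u_k* x0)
  bu <- Conj(sys$observation) %*% U            # 1 x K
  ux <- Conj(t(U)) %*% sys$initial_state       # K x 1
  as.vector(bu) * as.vector(ux)
}

#' Exact resonance representation of a linear system's observation
#'
#' Maps each eigenmode to a resonance: \eqn{\omega_k = i\lambda_k} (so
#' \eqn{\phi_k = -\mathrm{Im}\,\lambda_k}, \eqn{\gamma_k =
#' \mathrm{Re}\,\lambda_k}, negative for a damped system) with complex
#' amplitude \eqn{d_k = b^* P_k x(0)}. \code{\link{eval_time}} of the
#' result reproduces \code{\link{simulate_observation}} exactly. Modes
#' whose amplitude is exactly zero are kept (amplitude 0) so the
#' correspondence with the system's K modes is one-to-one.
#'
#' @param sys A \code{\link{linear_system_spec}}.
#' @return A \code{\link{resonance_spectrum}} with K resonances.
#' @export
resonances_from_system <- function(sys) {
  stopifnot(inherits(sys, "linear_system_spec"))
  d <- modal_amplitudes(sys)
  # omega = i * lambda: freq = -Im(lambda), decay = Re(lambda)
  spectrum_from_params(Mod(d), Arg(d),
                       -Im(sys$eigenvalues), Re(sys$eigenvalues),
                       label = "linear-system observation")
}
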