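#' Pearson product-moment correlation
#'
#' Thin validated wrapper over \code{stats::cor}: the correlation the
#' profile fits maximize. Invariant under positive-slope affine transforms
#' of either argument, which is why the tonal models never need scale or
#' location parameters.
#'
#' @param a,b Equal-length numeric vectors, length >= 3, each with nonzero
#'   variance.
#' @return Real scalar in \eqn{[-1, 1]}.
#' @export
pearson_correlation <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b) || length(a) < 3L)
    stop("pearson_correlation needs equal-length vectors of length >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("pearson_correlation is undefined for a zero-variance vector")
  stats::cor(a, b)
}

# ---- parameter transforms (unbounded <-> bounded) --------------------------

.unit <- function(u) 1 / (1 + exp(-u))
.unit_inv <- function(p) log(p / (1 - p))
.from_unit <- function(p, lo, hi, log_scale = FALSE) {
  if (log_scale) exp(log(lo) + p * (log(hi) - log(lo))) else lo + p * (hi - lo)
}

# default box bounds for the free parameters
default_fit_bounds <- function() list(
  gamma0 = c(1e-3, 0.5),
  d2 = c(0, 1), d3 = c(0, 1),
  alpha = c(0.01, 4), beta = c(-0.9, 20)
)

# amplitude bounds are mapped through a slightly shrunk unit interval so the
# logistic transform never has to reach an infinite argument at d = 0 or 1
.amp_from_unit <- function(p, lo, hi) lo + (hi - lo) * p
.squash <- function(p) 1e-6 + (1 - 2e-6) * p

# ---- fast model vectors ----------------------------------------------------
#
# The fitting objective evaluates the tonal model thousands of times, so
# these internal routines work directly on frequency/amplitude vectors
# (all phases are 0 and every decay is the shared gamma0 in the tonal
# models, so the pairwise closed form needs only real amplitude outer
# products and a common 2i*gamma0 in the denominator). They are checked
# against the object-based route (apply_harmonic + inner_product) in the
# tests.

# Re<Hf|Hg> for flat-phase, shared-decay spectra given overtone
# frequency/amplitude vectors. With all phases 0 and a common gamma0 > 0
# the real part of each pairwise term i a_j a_k / (D_jk + 2i gamma0)
# reduces to a_j a_k * 2 gamma0 / (D_jk^2 + 4 gamma0^2), a real
# Lorentzian kernel in the frequency difference D_jk.
.re_ip <- function(fa, ff, ga, gf, gamma0) {
  D <- outer(ff, gf, `-`)
  as.numeric(fa %*% (2 * gamma0 / (D * D + 4 * gamma0^2)) %*% ga)
}

# overtone frequencies/amplitudes of a triad at tonic 2^(off/12)
.triad_overtones <- function(off, quality, d2, d3, h) {
  semis <- if (quality == "major") c(0, 4, 7) else c(0, 3, 7)
  tf <- 2^((off + semis) / 12)
  N <- h$n_overtones
  n <- rep(seq_len(N), times = 3)
  freq <- n * rep(tf, each = N)
  amp <- attenuation_weight(h$attenuation, n, overtone_freq = freq) *
    rep(c(1, d2, d3), each = N)
  list(freq = freq, amp = amp)
}

.pitch_overtones <- function(off, h) {
  N <- h$n_overtones
  n <- seq_len(N)
  freq <- n * 2^(off / 12)
  list(freq = freq,
       amp = attenuation_weight(h$attenuation, n, overtone_freq = freq))
}

# 24-vector: C-major affinity profile (12) followed by C-minor (12)
affinity_model_vector <- function(gamma0, d2, d3, h) {
  pitches <- lapply(0:11, .pitch_overtones, h = h)
  pnorm <- vapply(pitches, function(p)
    sqrt(.re_ip(p$amp, p$freq, p$amp, p$freq, gamma0)), numeric(1))
  out <- numeric(0)
  for (q in c("major", "minor")) {
    tr <- .triad_overtones(0, q, d2, d3, h)
    tnorm <- sqrt(.re_ip(tr$amp, tr$freq, tr$amp, tr$freq, gamma0))
    vals <- vapply(1:12, function(i) {
      p <- pitches[[i]]
      .re_ip(tr$amp, tr$freq, p$amp, p$freq, gamma0) / (tnorm * pnorm[i])
    }, numeric(1))
    out <- c(out, vals)
  }
  out
}

# 48-vector: the four distance panels (major-major, major-minor,
# minor-major, minor-minor), each 12 semitone offsets
distance_model_vector <- function(gamma0, d2, d3, h) {
  majors <- lapply(0:11, .triad_overtones, quality = "major",
                   d2 = d2, d3 = d3, h = h)
  minors <- lapply(0:11, .triad_overtones, quality = "minor",
                   d2 = d2, d3 = d3, h = h)
  nrm <- function(t) sqrt(.re_ip(t$amp, t$freq, t$amp, t$freq, gamma0))
  norms_M <- vapply(majors, nrm, numeric(1))
  norms_m <- vapply(minors, nrm, numeric(1))
  panel <- function(ref, nref, targets, ntargets)
    1 - vapply(seq_along(targets), function(i)
      .re_ip(ref$amp, ref$freq, targets[[i]]$amp, targets[[i]]$freq, gamma0) /
        (nref * ntargets[i]), numeric(1))
  c(panel(majors[[1]], norms_M[1], majors, norms_M),
    panel(majors[[1]], norms_M[1], minors, norms_m),
    panel(minors[[1]], norms_m[1], majors, norms_M),
    panel(minors[[1]], norms_m[1], minors, norms_m))
}

# flatten a targets list (vectors or tonal_profiles) to one numeric vector
flatten_targets <- function(targets, model_kind) {
  want <- if (model_kind == "affinity") c("major", "minor") else
    c("major_major", "major_minor", "minor_major", "minor_minor")
  if (!is.list(targets) || !all(want %in% names(targets)))
    stop("targets must be a named list with elements: ",
         paste(want, collapse = ", "))
  unlist(lapply(targets[want], function(p) {
    v <- if (inherits(p, "tonal_profile")) p$values else as.numeric(p)
    if (length(v) != 12L) stop("each target profile must have 12 entries")
    if (any(!is.finite(v))) stop("target profiles must be finite")
    v
  }), use.names = FALSE)
}

#' Fit the tonal model to target profiles by correlation
#'
#' Maximizes the Pearson correlation between the model's profile vector
#' and the targets over the free parameters (gamma0, d2, d3, plus alpha
#' and beta when the attenuation family is \code{power_law}). Because
#' correlation is affine-invariant, no scale or location parameters are
#' estimated. The optimizer is a multi-start Nelder-Mead simplex
#' (derivative-free) on logit/log-transformed parameters, started from a
#' fixed 3 x 3 x 3 grid over the bounds, so results are deterministic.
#'
#' @param targets Named list of target profiles (numeric 12-vectors or
#'   \code{\link{tonal_profile}}s): \code{major} and \code{minor} for
#'   \code{model_kind = "affinity"}; \code{major_major},
#'   \code{major_minor}, \code{minor_major}, \code{minor_minor} for
#'   \code{"distance"}. The objective concatenates them (24- or
#'   48-vector).
#' @param model_kind \code{"affinity"} or \code{"distance"}.
#' @param attenuation_family \code{"constant"} (flat, default: the form
#'   the fitted model settles on) or \code{"power_law"} (frees alpha,
#'   beta).
#' @param n_overtones Overtone count N of the harmonic expansion
#'   (default 12).
#' @param bounds Optional named list overriding entries of the default
#'   box bounds (\code{gamma0} in [1e-3, 0.5]; \code{d2}, \code{d3} in
#'   [0, 1]; \code{alpha} in [0.01, 4]; \code{beta} in [-0.9, 20]).
#' @param seed Integer master seed; recorded in the result and used only
#'   for extra random starts beyond the deterministic grid.
#' @param starts Number of starts (default 27 = the full grid; fewer uses
#'   a deterministic prefix, more adds seeded random starts).
#' @param maxit,reltol Nelder-Mead control.
#' @return An object of class \code{"fit_result"}: fitted \code{gamma0},
#'   \code{d2}, \code{d3}, \code{attenuation} (an
#'   \code{\link{attenuation_spec}}), \code{n_overtones}, per-profile and
#'   overall correlations (\code{correlation_major},
#'   \code{correlation_minor}, \code{correlation_both}),
#'   \code{objective_evals}, \code{seed}, \code{converged}.
#' @export
fit_profile_model <- function(targets,
                              model_kind = c("affinity", "distance"),
                              attenuation_family = c("constant", "power_law"),
                              n_overtones = 12,
                              bounds = NULL, seed = 1L, starts = 27L,
                              maxit = 2000L, reltol = 1e-12) {
  model_kind <- match.arg(model_kind)
  attenuation_family <- match.arg(attenuation_family)
  target_vec <- flatten_targets(targets, model_kind)
  b <- default_fit_bounds()
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  free_att <- attenuation_family == "power_law"
  npar <- if (free_att) 5L else 3L

  decode <- function(u) {
    p <- .unit(u)
    out <- list(
      gamma0 = .from_unit(p[1], b$gamma0[1], b$gamma0[2], log_scale = TRUE),
      d2 = .amp_from_unit(.squash(p[2]), b$d2[1], b$d2[2]),
      d3 = .amp_from_unit(.squash(p[3]), b$d3[1], b$d3[2]))
    if (free_att) {
      out$alpha <- .from_unit(p[4], b$alpha[1], b$alpha[2])
      out$beta <- .from_unit(p[5], b$beta[1], b$beta[2])
    }
    out
  }
  make_h <- function(par) {
    att <- if (free_att)
      attenuation_spec("power_law", alpha = par$alpha, beta = par$beta)
    else attenuation_spec("constant")
    harmonic_spec(n_overtones, att)
  }
  model_vec <- function(par) {
    h <- make_h(par)
    if (model_kind == "affinity")
      affinity_model_vector(par$gamma0, par$d2, par$d3, h)
    else
      distance_model_vector(par$gamma0, par$d2, par$d3, h)
  }

  evals <- 0L
  objective <- function(u) {
    evals <<- evals + 1L
    par <- decode(u)
    m <- model_vec(par)
    if (stats::sd(m) == 0) return(1)  # degenerate model: worst objective
    -stats::cor(m, target_vec)
  }

  # deterministic 3x3x3 start grid on the unit cube (free attenuation
  # parameters start from the cube centre)
  g <- .unit_inv(c(0.25, 0.5, 0.75))
  grid <- as.matrix(expand.grid(g, g, g))
  if (free_att) grid <- cbind(grid, 0, 0)
  if (starts < nrow(grid)) grid <- grid[seq_len(starts), , drop = FALSE]
  if (starts > nrow(grid)) {
    set.seed(seed)
    extra <- matrix(stats::rnorm((starts - nrow(grid)) * npar, sd = 1.5),
                    ncol = npar)
    grid <- rbind(grid, extra)
  }

  best <- NULL
  converged <- FALSE
  for (i in seq_len(nrow(grid))) {
    o <- stats::optim(grid[i, ], objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
    if (is.null(best) || o$value < best$value) {
      best <- o
      converged <- o$convergence == 0L
    }
  }

  par <- decode(best$par)
  m <- model_vec(par)
  if (model_kind == "affinity") {
    cm <- stats::cor(m[1:12], target_vec[1:12])
    cn <- stats::cor(m[13:24], target_vec[13:24])
  } else {
    cm <- stats::cor(m[1:24], target_vec[1:24])
    cn <- stats::cor(m[25:48], target_vec[25:48])
  }
  structure(list(
    gamma0 = par$gamma0, d2 = par$d2, d3 = par$d3,
    attenuation = if (free_att)
      attenuation_spec("power_law", alpha = par$alpha, beta = par$beta)
    else attenuation_spec("constant"),
    n_overtones = as.integer(n_overtones),
    model_kind = model_kind,
    correlation_major = cm, correlation_minor = cn,
    correlation_both = stats::cor(m, target_vec),
    objective_evals = evals, seed = as.integer(seed),
    converged = converged),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "Tonal %s model fit (N = %d, %s attenuation)\n", x$model_kind,
    x$n_overtones, x$attenuation$family))
  cat(sprintf("  gamma0 = %.4f, d2 = %.3f, d3 = %.3f\n", x$gamma0, x$d2, x$d3))
  if (x$attenuation$family == "power_law")
    cat(sprintf("  alpha = %.3f, beta = %.3f\n",
                x$attenuation$alpha, x$attenuation$beta))
  cat(sprintf("  correlations: %.3f / %.3f (panels), %.3f (overall); %d evals\n",
              x$correlation_major, x$correlation_minor, x$correlation_both,
              x$objective_evals))
  invisible(x)
}

#' Best-fit correlation as a function of overtone count
#'
#' For each N in \code{n_range}, fits the flat-attenuation (constant
#' A = 1) model to the affinity targets and, if supplied, the distance
#' targets, and records the best correlations and their mean. The location
#' of the maximum of the mean curve identifies the overtone count the
#' data favour.
#'
#' @param targets_affinity Affinity targets (see
#'   \code{\link{fit_profile_model}}), or NULL to skip.
#' @param targets_distance Distance targets, or NULL to skip.
#' @param n_range Integer vector of overtone counts (subset of 1..25).
#' @param seed,starts,maxit,reltol Passed to \code{\link{fit_profile_model}}.
#' @return A data.frame with columns \code{n}, \code{cor_affinity},
#'   \code{cor_distance}, \code{cor_mean} (mean of the available curves).
#' @export
sweep_overtone_count <- function(targets_affinity = NULL,
                                 targets_distance = NULL,
                                 n_range = 1:25, seed = 1L, starts = 27L,
                                 maxit = 2000L, reltol = 1e-12) {
  stopifnot(all(n_range >= 1), all(n_range <= 25),
            all(n_range == round(n_range)))
  if (is.null(targets_affinity) && is.null(targets_distance))
    stop("at least one of targets_affinity, targets_distance is required")
  one <- function(targets, kind, N) {
    if (is.null(targets)) return(NA_real_)
    fit_profile_model(targets, kind, "constant", n_overtones = N,
                      seed = seed, starts = starts, maxit = maxit,
                      reltol = reltol)$correlation_both
  }
  ca <- vapply(n_range, function(N) one(targets_affinity, "affinity", N),
               numeric(1))
  cd <- vapply(n_range, function(N) one(targets_distance, "distance", N),
               numeric(1))
  data.frame(n = as.integer(n_range), cor_affinity = ca, cor_distance = cd,
             cor_mean = rowMeans(cbind(ca, cd), na.rm = TRUE))
}

#' Score fixed distance-model parameters against a target profile set
#'
#' Evaluates the inter-key distance model at the supplied parameters (no
#' refitting) and reports the Pearson correlation between the model's
#' concatenated distance panels and the targets. This is how a fitted
#' parameterization is evaluated against an independent distance data set.
#'
#' @param targets Distance targets: named list with \code{major_major},
#'   \code{major_minor}, \code{minor_major}, \code{minor_minor}
#'   12-vectors, or a plain numeric vector matched by position against the
#'   model's 48-vector (or any of its prefixes of length 12, 24, 36).
#' @param gamma0,d2,d3 Model parameters.
#' @param n_overtones Overtone count (default 12).
#' @return The Pearson correlation (real scalar).
#' @export
score_distance_fixture <- function(targets, gamma0, d2, d3, n_overtones = 12) {
  h <- harmonic_spec(n_overtones, attenuation_spec("constant"))
  m <- distance_model_vector(gamma0, d2, d3, h)
  v <- if (is.list(targets)) flatten_targets(targets, "distance")
       else as.numeric(targets)
  if (length(v) %% 12 != 0 || length(v) < 12 || length(v) > 48)
    stop("distance targets must supply 12, 24, 36 or 48 values")
  pearson_correlation(v, m[seq_along(v)])
}
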