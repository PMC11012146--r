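#' Load a tonal profile fixture from CSV
#'
#' The profile CSV schema is two columns, \code{semitone_offset} (0-11, in
#' order) and \code{value}. The loader validates length, numeric type and
#' finiteness and names the offending file and row in its errors.
#'
#' @param path Path to the CSV.
#' @param expected_kind \code{"affinity"}, \code{"distance"} or
#'   \code{"rating"} (unconstrained scale, e.g. probe-tone ratings).
#' @return A \code{\link{tonal_profile}}.
#' @export
load_profile_fixture <- function(path, expected_kind = "rating") {
  x <- utils::read.csv(path)
  if (nrow(x) == 0L) stop("empty profile fixture (header only): ", path)
  if (!all(c("semitone_offset", "value") %in% names(x)))
    stop("profile fixture needs columns semitone_offset, value: ", path)
  if (nrow(x) != 12L)
    stop(sprintf("profile fixture %s has %d rows, expected 12", path, nrow(x)))
  if (!is.numeric(x$value))
    stop("non-numeric value column in profile fixture: ", path)
  bad <- which(!is.finite(x$value))
  if (length(bad))
    stop(sprintf("non-finite value at row %d of %s", bad[1], path))
  if (!identical(as.integer(x$semitone_offset), 0:11))
    stop("semitone_offset must be 0..11 in order: ", path)
  tonal_profile(x$value, expected_kind)
}

#' Write a tonal profile to CSV
#'
#' Columns \code{semitone_offset}, \code{value}.
#'
#' @param profile A \code{\link{tonal_profile}} or numeric 12-vector.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  v <- if (inherits(profile, "tonal_profile")) profile$values
       else as.numeric(profile)
  stopifnot(length(v) == 12L)
  # 17 significant digits: lossless decimal round trip for doubles
  df <- data.frame(semitone_offset = 0:11,
                   value = formatC(v, digits = 17, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Krumhansl-Kessler probe-tone profiles
#'
#' The classic 1982 probe-tone rating profiles for major and minor keys
#' (mean goodness-of-fit ratings, 12 semitones from the tonic), shipped as
#' a plain-text transcription in \code{inst/extdata/}. These are the
#' empirical targets the key-affinity model is fitted against.
#'
#' @return A list with numeric 12-vectors \code{major} and \code{minor}.
#' @export
kk_profiles <- function() {
  dir <- system.file("extdata", package = "resotone", mustWork = TRUE)
  list(
    major = load_profile_fixture(file.path(dir, "kk_major_profile.csv"))$values,
    minor = load_profile_fixture(file.path(dir, "kk_minor_profile.csv"))$values
  )
}

#' Generate synthetic fitting targets from known parameters
#'
#' Evaluates the tonal model at the supplied true parameters and adds
#' seeded Gaussian noise, producing targets in the shape
#' \code{\link{fit_profile_model}} expects. This is the stand-in for
#' external empirical fixtures in parameter-recovery tests: the whole
#' pipeline runs with no external data.
#'
#' @param true_params List (or \code{\link{triad_spec}}) with
#'   \code{gamma0}, \code{d2}, \code{d3}.
#' @param model_kind \code{"affinity"} (24 values: major then minor
#'   profile) or \code{"distance"} (48 values: four panels).
#' @param noise_sd Non-negative standard deviation of additive Gaussian
#'   noise on the similarity/distance values.
#' @param seed Integer seed.
#' @param n_overtones Overtone count of the generating model (default 12).
#' @return A named list of numeric 12-vectors matching the fitting target
#'   shape (\code{major}/\code{minor} or the four distance panels).
#' @export
generate_synthetic_targets <- function(true_params,
                                       model_kind = c("affinity", "distance"),
                                       noise_sd = 0, seed = 1L,
                                       n_overtones = 12) {
  model_kind <- match.arg(model_kind)
  stopifnot(noise_sd >= 0)
  gamma0 <- true_params$gamma0
  d2 <- true_params$d2
  d3 <- true_params$d3
  stopifnot(is.numeric(gamma0), gamma0 > 0,
            is.numeric(d2), is.numeric(d3))
  h <- harmonic_spec(n_overtones, attenuation_spec("constant"))
  m <- if (model_kind == "affinity") affinity_model_vector(gamma0, d2, d3, h)
       else distance_model_vector(gamma0, d2, d3, h)
  set.seed(seed)
  m <- m + stats::rnorm(length(m), sd = noise_sd)
  if (model_kind == "affinity")
    list(major = m[1:12], minor = m[13:24])
  else
    list(major_major = m[1:12], major_minor = m[13:24],
         minor_major = m[25:36], minor_minor = m[37:48])
}
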