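# the best-fit key-affinity parameterization used in several checks
best_fit_key <- function(quality = "major")
  triad_spec(quality, tonic_freq = 1, d2 = 0.672, d3 = 0.420, gamma0 = 0.0309)

test_that("equal-tempered semitone frequencies", {
  expect_equal(semitone_frequency(0), 1)
  expect_equal(semitone_frequency(12), 2)
  expect_equal(semitone_frequency(7), 2^(7 / 12))
  expect_equal(semitone_frequency(-12, 440), 220)
})

test_that("triad spectra place the triad tones with shared decay", {
  maj <- resotone:::spectrum_params(triad_spectrum(triad_spec("major", d2 = 0.7, d3 = 0.4, gamma0 = 0.03)))
  expect_equal(maj$freq, 2^(c(0, 4, 7) / 12))
  expect_equal(maj$amp_mag, c(1, 0.7, 0.4))
  expect_equal(maj$decay, rep(0.03, 3))
  expect_equal(maj$phase, rep(0, 3))
  min_ <- resotone:::spectrum_params(triad_spectrum(triad_spec("minor")))
  expect_equal(min_$freq, 2^(c(0, 3, 7) / 12))
  expect_equal(min_$amp_mag, c(1, 1, 1))
  just <- resotone:::spectrum_params(triad_spectrum(triad_spec("major", tuning = "just")))
  expect_equal(just$freq, c(1, 5 / 4, 3 / 2))
})

test_that("pitch spectra are single positive-decay resonances", {
  p <- pitch_spectrum(1, 0.0309)
  expect_equal(length(p), 1L)
  expect_gt(spectrum_norm(p), 0)
  key <- best_fit_key()
  expect_lt(key_affinity(key, 1), 1)  # triad and pitch are never identical
})

test_that("key affinity ranks triad tones above the tritone", {
  key <- best_fit_key()
  h <- harmonic_spec(12)
  tonic <- key_affinity(key, semitone_frequency(0), h)
  fifth <- key_affinity(key, semitone_frequency(7), h)
  tritone <- key_affinity(key, semitone_frequency(6), h)
  octave <- key_affinity(key, semitone_frequency(12), h)
  expect_gt(tonic, tritone)
  expect_gt(fifth, tritone)
  expect_gt(octave, tritone)  # octave quasi-equivalence
})

test_that("affinity is invariant under transposition (common dilation)", {
  h <- harmonic_spec(12)
  a0 <- key_affinity(best_fit_key(), semitone_frequency(4), h)
  for (c0 in c(0.5, 3, 11)) {
    keyc <- triad_spec("major", tonic_freq = c0, d2 = 0.672, d3 = 0.420,
                       gamma0 = 0.0309 * c0)
    expect_equal(key_affinity(keyc, c0 * semitone_frequency(4), h), a0,
                 tolerance = 1e-10)
  }
})

test_that("affinity profiles are 12 bounded values with a tritone dip", {
  prof <- affinity_profile(best_fit_key(), harmonic_spec(12))
  expect_s3_class(prof, "tonal_profile")
  expect_length(prof$values, 12)
  expect_true(all(prof$values >= -1 & prof$values <= 1))
  expect_gte(prof$values[1], prof$values[7])  # tonic vs tritone
})

test_that("the affinity sweep peaks near the triad tones", {
  sw <- affinity_sweep(best_fit_key(), harmonic_spec(12), n_points = 601)
  expect_equal(nrow(sw), 601)
  expect_true(all(diff(sw$freq) > 0))
  # both endpoints (tonic and octave) are high-affinity peaks relative to
  # the tritone region between them
  offs <- 12 * log2(sw$freq)
  tritone_max <- max(sw$affinity[abs(offs - 6) < 0.5])
  expect_gt(sw$affinity[1], tritone_max)
  expect_gt(sw$affinity[601], tritone_max)
  # local maxima within half a semitone of offsets 0, 4, 7
  v <- sw$affinity
  locmax <- which(diff(sign(diff(v))) == -2) + 1L
  peak_offsets <- offs[c(1L, locmax, nrow(sw))]
  for (o in c(0, 4, 7))
    expect_true(any(abs(peak_offsets - o) < 0.5))
})

test_that("sweep peak width at 90% height grows with gamma0", {
  h <- harmonic_spec(12)
  width_at <- function(gamma0) {
    key <- triad_spec("major", d2 = 0.672, d3 = 0.420, gamma0 = gamma0)
    sw <- affinity_sweep(key, h, n_points = 1201)
    v <- sw$affinity
    i0 <- which.max(v[1:200])               # the tonic peak
    thresh <- 0.9 * v[i0]
    lo <- i0; while (lo > 1 && v[lo - 1] >= thresh) lo <- lo - 1
    hi <- i0; while (hi < length(v) && v[hi + 1] >= thresh) hi <- hi + 1
    log2(sw$freq[hi] / sw$freq[lo])
  }
  w <- vapply(c(0.01, 0.03, 0.1), width_at, numeric(1))
  expect_true(all(diff(w) > 0))
})

test_that("the illustrative sweep preset carries 1/n attenuation at N = 50", {
  pre <- illustrative_sweep_preset()
  expect_equal(pre$h$n_overtones, 50L)
  expect_equal(attenuation_weight(pre$h$attenuation, 2), 0.5)
  expect_equal(pre$key$gamma0, 0.01)
})

test_that("inter-key distance is a symmetric premetric with zero self-distance", {
  h <- harmonic_spec(12)
  key <- triad_spec("major", d2 = 0.925, d3 = 1, gamma0 = 0.0402)
  expect_equal(inter_key_distance(key, key, h), 0)
  set.seed(15)
  for (i in 1:5) {
    a <- triad_spec(sample(c("major", "minor"), 1),
                    tonic_freq = semitone_frequency(sample(0:11, 1)),
                    d2 = 0.925, d3 = 1, gamma0 = 0.0402)
    b <- triad_spec(sample(c("major", "minor"), 1),
                    tonic_freq = semitone_frequency(sample(0:11, 1)),
                    d2 = 0.925, d3 = 1, gamma0 = 0.0402)
    expect_equal(inter_key_distance(a, b, h), inter_key_distance(b, a, h))
    expect_gte(inter_key_distance(a, b, h), 0)
  }
})

test_that("the dominant is closer to the tonic key than the tritone key", {
  h <- harmonic_spec(12)
  C <- triad_spec("major", d2 = 0.925, d3 = 1, gamma0 = 0.0402)
  G <- triad_spec("major", tonic_freq = semitone_frequency(7),
                  d2 = 0.925, d3 = 1, gamma0 = 0.0402)
  Fs <- triad_spec("major", tonic_freq = semitone_frequency(6),
                   d2 = 0.925, d3 = 1, gamma0 = 0.0402)
  expect_lt(inter_key_distance(C, G, h), inter_key_distance(C, Fs, h))
})

test_that("distance profile sets give the four 12-element panels", {
  ref <- triad_spec("major", d2 = 0.925, d3 = 1, gamma0 = 0.0402)
  h <- harmonic_spec(12)
  set_ <- distance_profile_set(ref, h)
  expect_named(set_, c("major_major", "major_minor", "minor_major", "minor_minor"))
  for (p in set_) {
    expect_s3_class(p, "tonal_profile")
    expect_length(p$values, 12)
    expect_true(all(p$values >= 0 & p$values <= 2))
  }
  expect_equal(set_$major_major$values[1], 0)
  expect_equal(set_$minor_minor$values[1], 0)
  # panels agree with direct pairwise distances
  Eb <- triad_spec("minor", tonic_freq = semitone_frequency(3),
                   d2 = 0.925, d3 = 1, gamma0 = 0.0402)
  expect_equal(set_$major_minor$values[4], inter_key_distance(ref, Eb, h))
})

test_that("the 24 x 24 distance matrix is symmetric with zero diagonal", {
  h <- harmonic_spec(4)  # small N keeps this cheap
  m <- inter_key_distance_matrix(triad_spec("major", d2 = 0.9, d3 = 1,
                                            gamma0 = 0.04), h)
  expect_equal(dim(m), c(24L, 24L))
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(rep(0, 24), rownames(m)))
})

test_that("tonal profiles validate their kind-specific ranges", {
  expect_error(tonal_profile(1:11, "affinity"), "exactly 12")
  expect_error(tonal_profile(c(rep(0, 11), 1.5), "affinity"), "\\[-1, 1\\]")
  expect_error(tonal_profile(c(rep(0, 11), 2.5), "distance"), "\\[0, 2\\]")
  expect_silent(tonal_profile(seq(1, 7, length.out = 12), "rating"))
})
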