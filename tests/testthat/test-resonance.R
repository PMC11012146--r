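test_that("construction enforces the resonance invariants", {
  expect_error(resonance(-1, 0, 1, 0.5), "non-negative")
  expect_error(resonance(1, 0, 1, 0), "nonzero")
  expect_error(resonance_spectrum(list()), "non-empty")
  expect_silent(resonance(0, 0, 1, -0.3))  # zero amplitude is allowed
})

test_that("time-domain evaluation matches the damped-oscillator form", {
  f <- example_resonance_spectrum()
  expect_equal(eval_time(f, 0), 2 + 0i)
  expect_equal(eval_time(f, 1), 2 * exp(-1) * (cos(10) - 1i * sin(10)))
  zero <- spectrum_from_params(c(0, 0), c(1, 2), c(3, 4), c(-1, -2))
  expect_equal(eval_time(zero, c(0, 0.5, 2)), rep(0 + 0i, 3))
  expect_identical(eval_time(f, numeric(0)), complex(0))
})

test_that("frequency-domain evaluation is a Lorentzian peak at the pole", {
  f <- example_resonance_spectrum()
  expect_equal(eval_freq(f, 10), complex(real = 2 / sqrt(2 * pi)))
  grid <- seq(0, 20, by = 0.05)
  expect_equal(grid[which.max(Mod(eval_freq(f, grid)))], 10)
  expect_lt(Mod(eval_freq(f, 1e6)), 1e-5)  # 1/phi tail
})

test_that("closed-form inner product matches its simplest exact values", {
  expect_equal(inner_product(single(decay = 0.5), single(decay = 0.5)), 1 + 0i)
  f <- example_resonance_spectrum()
  expect_equal(inner_product(f, f), 2 + 0i)  # |d|^2/(2|gamma|) = 4/2
})

test_that("opposite-decay-sign spectra are exactly orthogonal", {
  set.seed(11)
  for (i in 1:10) {
    f <- random_spectrum(decay_sign = 1)
    g <- random_spectrum(decay_sign = -1)
    expect_identical(Mod(inner_product(f, g)), 0)
    expect_identical(Mod(inner_product(g, f)), 0)
  }
  # mixed-sign spectra: only same-sign pairs contribute
  up <- single(1, 0.3, 2, 0.4)
  down <- single(1.5, -0.2, 5, -0.7)
  mixed <- concat_spectra(up, down)
  expect_equal(inner_product(mixed, up), inner_product(up, up))
  expect_equal(inner_product(mixed, mixed),
               inner_product(up, up) + inner_product(down, down))
})

test_that("the inner product is Hermitian and positive definite", {
  set.seed(7)
  for (i in 1:20) {
    f <- random_spectrum()
    g <- random_spectrum()
    expect_equal(inner_product(f, g), Conj(inner_product(g, f)))
    self <- inner_product(f, f)
    expect_lt(abs(Im(self)) / Re(self), 1e-12)
    expect_gt(Re(self), 0)
  }
})

test_that("norm is homogeneous and matches the closed form", {
  expect_equal(spectrum_norm(example_resonance_spectrum())^2, 2)
  expect_equal(spectrum_norm(single(decay = 0.5))^2, 1)
  set.seed(3)
  f <- random_spectrum(3)
  expect_equal(spectrum_norm(scale_spectrum(f, 3.7)),
               3.7 * spectrum_norm(f))
})

test_that("cosine similarity has the inner-product geometry", {
  set.seed(5)
  f <- random_spectrum(3)
  g <- random_spectrum(4)
  expect_equal(cosine_similarity(f, f), 1)
  s <- cosine_similarity(f, g)
  expect_gte(s, -1)
  expect_lte(s, 1)
  expect_equal(s, cosine_similarity(g, f))
  # invariant under positive rescaling of either argument
  expect_equal(cosine_similarity(scale_spectrum(f, 5), g), s)
  expect_equal(cosine_similarity(f, scale_spectrum(g, 0.2)), s)
  # orthogonal spectra have similarity 0, distance 1
  up <- random_spectrum(decay_sign = 1)
  down <- random_spectrum(decay_sign = -1)
  expect_identical(cosine_similarity(up, down), 0)
  expect_identical(cosine_distance(up, down), 1)
  expect_equal(cosine_distance(f, f), 0)
  expect_equal(cosine_distance(f, g), cosine_distance(g, f))
})

test_that("similarity falls as single resonances move apart in frequency", {
  near <- cosine_similarity(single(freq = 1, decay = 0.05),
                            single(freq = 1.1, decay = 0.05))
  far <- cosine_similarity(single(freq = 1, decay = 0.05),
                           single(freq = 11, decay = 0.05))
  expect_gt(near, far)
})

test_that("similarity is invariant under frequency-axis dilation", {
  set.seed(13)
  for (i in 1:10) {
    f <- random_spectrum(3)
    g <- random_spectrum(3)
    c0 <- runif(1, 0.2, 8)
    dilate <- function(s) {
      p <- resotone:::spectrum_params(s)
      spectrum_from_params(p$amp_mag, p$phase, c0 * p$freq, c0 * p$decay)
    }
    expect_equal(cosine_similarity(dilate(f), dilate(g)),
                 cosine_similarity(f, g), tolerance = 1e-10)
  }
})

test_that("quadrature oracle confirms the closed form on random spectra", {
  set.seed(29)
  for (i in 1:15) {
    f <- random_spectrum()
    g <- random_spectrum()
    cf <- inner_product(f, g)
    q <- quadrature_inner_product(f, g, halfwidth = 1e4)
    expect_lt(Mod(cf - q) / Mod(cf), 1e-6)
  }
  # the worked example's squared norm, by quadrature
  f1 <- example_resonance_spectrum()
  expect_equal(Re(quadrature_inner_product(f1, f1, 1e4)), 2, tolerance = 1e-7)
})

test_that("spectrum JSON round-trips bit-identically", {
  set.seed(17)
  f <- random_spectrum(4)
  path <- withr::local_tempfile(fileext = ".json")
  write_spectrum_json(f, path)
  g <- read_spectrum_json(path)
  expect_identical(resotone:::spectrum_params(g), resotone:::spectrum_params(f))
  tt <- seq(0, 3, length.out = 7)
  expect_identical(eval_time(g, tt), eval_time(f, tt))
})

test_that("spectrum JSON reader rejects zero decay", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"label":"bad","resonances":[{"amp":1,"phase":0,"freq":2,"decay":0}]}',
             path)
  expect_error(read_spectrum_json(path), "decay == 0")
})
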