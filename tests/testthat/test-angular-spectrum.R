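make_gaussian_plane <- function(n = 64, h = 0.25, f = 940e3, width = 4,
                                focus = NULL) {
  x <- (seq_len(n) - (n + 1) / 2) * h
  r2 <- outer(x^2, x^2, `+`)
  v <- exp(-r2 / width^2) + 0i
  if (!is.null(focus)) {
    k <- 2 * pi * f / 1482 / 1e3
    v <- v * exp(1i * k * (sqrt(r2 + focus^2) - focus))
  }
  pressure_plane(v, h, 0, f)
}

test_that("zero-distance propagation is the identity to machine precision", {
  pl <- make_gaussian_plane()
  out <- angular_spectrum_step(pl, 0, 1482)
  expect_lt(max(Mod(out$values - pl$values)), 1e-12 * max(Mod(pl$values)))
})

test_that("a normally incident plane wave advances by exactly e^{-j2pi f d/c}", {
  n <- 32; f <- 1e6; c0 <- 1500; d <- 7.3
  pl <- pressure_plane(matrix(2 + 1i, n, n), 0.5, 0, f)
  out <- angular_spectrum_step(pl, d, c0)  # no pad/taper: field is periodic
  expected <- (2 + 1i) * exp(-1i * 2 * pi * f * d * 1e-3 / c0)
  expect_lt(max(Mod(out$values - expected)), 1e-10)
})

test_that("plane-wave amplitude follows Beer-Lambert in a lossy medium", {
  n <- 16; f <- 940e3; d <- 30
  pl <- pressure_plane(matrix(1 + 0i, n, n), 0.5, 0, f)
  out <- angular_spectrum_step(pl, d, GEL$speed_of_sound, ALPHA_GEL_940)
  expect_equal(Mod(out$values[1, 1]), exp(-ALPHA_GEL_940 * 0.03),
               tolerance = 1e-10)
})

test_that("forward then backward propagation restores the field (unitarity)", {
  pl <- make_gaussian_plane()
  # the truncated Gaussian carries an evanescent spectral tail (~1e-3) that
  # "zero" removes; one round trip projects onto the propagating subspace,
  # on which the propagator must then be exactly unitary
  p0 <- angular_spectrum_step(
    angular_spectrum_step(pl, 11, 1482, evanescent = "zero"),
    -11, 1482, evanescent = "zero")
  fwd <- angular_spectrum_step(p0, 11, 1482, evanescent = "zero")
  back <- angular_spectrum_step(fwd, -11, 1482, evanescent = "zero")
  expect_lt(max(Mod(back$values - p0$values)) / max(Mod(p0$values)), 1e-10)
})

test_that("the propagator is linear", {
  pl <- make_gaussian_plane()
  s <- 3.7 - 2.2i
  a <- angular_spectrum_step(pl, 9, 1482)
  pl2 <- pressure_plane(pl$values * s, pl$pixel_size, 0, pl$frequency)
  b <- angular_spectrum_step(pl2, 9, 1482)
  expect_equal(b$values, a$values * s, tolerance = 1e-12)
})

test_that("plane-integrated power is conserved in lossless propagation", {
  pl <- make_gaussian_plane(n = 96, focus = NULL, width = 3)
  Z <- 998 * 1482
  p0 <- plane_power(pl, Z)
  for (d in c(3, 8)) {
    out <- angular_spectrum_step(pl, d, 1482, evanescent = "zero",
                                 pad_fraction = 0.5)
    expect_equal(plane_power(out, Z), p0, tolerance = 1e-3)
  }
})

test_that("non-finite fields are refused", {
  v <- matrix(1 + 0i, 8, 8); v[2, 2] <- NaN
  expect_error(pressure_plane(v, 0.5, 0, 1e6), "non-finite")
  pl <- make_gaussian_plane(n = 8)
  pl$values[1, 1] <- Inf
  expect_error(angular_spectrum_step(pl, 1, 1482), "non-finite")
})

test_that("fft_freq and next_fast_size behave like their standard definitions", {
  expect_equal(fft_freq(4, 1), c(0, 0.25, -0.5, -0.25))
  expect_equal(fft_freq(5, 0.5), c(0, 1, 2, -2, -1) / 2.5)
  expect_equal(next_fast_size(97L), 100L)
  expect_equal(next_fast_size(128L), 128L)
  expect_equal(next_fast_size(121L), 125L)
})

test_that("expand_plane_to_volume matches repeated single steps", {
  pl <- make_gaussian_plane(n = 48)
  zs <- c(2, 5, 9)
  vol <- expand_plane_to_volume(pl, zs, 1482, pad_fraction = 0.25)
  for (j in seq_along(zs)) {
    one <- angular_spectrum_step(pl, zs[j], 1482, pad_fraction = 0.25)
    expect_lt(max(Mod(vol$values[, , j] - one$values)), 1e-10)
  }
})
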