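test_that("trilinear resampling reproduces affine fields exactly", {
  d <- c(10, 12, 14); h <- 0.5
  ax <- lapply(seq_along(d), function(a) (seq_len(d[a]) - 1) * h)
  f <- outer(outer(2 * ax[[1]], -3 * ax[[2]], `+`), 0.7 * ax[[3]], `+`) + 5
  for (target in c(0.3, 0.5, 0.8)) {
    out <- resample_field(f, h, target)
    off <- attr(out, "offset")
    axo <- lapply(seq_along(dim(out)), function(a)
      off[a] + (seq_len(dim(out)[a]) - 1) * target)
    fo <- outer(outer(2 * axo[[1]], -3 * axo[[2]], `+`), 0.7 * axo[[3]], `+`) + 5
    expect_equal(as.vector(out), as.vector(fo), tolerance = 1e-10)
  }
})

test_that("RMSDn matches closed-form cases", {
  d <- c(45, 45, 45)
  ref <- array(0.5, d); ref[23, 23, 23] <- 1  # global max 1
  sim <- ref
  ctr <- c(23, 23, 23)
  expect_equal(rmsdn_pressure(sim, ref, ctr), 0)
  # single-delta: one voxel differs by 0.1 -> sqrt(0.1^2/41^3)*100
  sim[25, 23, 23] <- 0.6
  expect_equal(rmsdn_pressure(sim, ref, ctr),
               sqrt(0.01 / 41^3) * 100, tolerance = 1e-12)
  # constant offset c over the region -> c / max(ref) * 100
  sim <- ref + 0.03
  expect_equal(rmsdn_pressure(sim, ref, ctr), 3, tolerance = 1e-10)
  # the normalizer is the global reference max, not a region or self max
  ref2 <- ref; ref2[1, 1, 1] <- 2
  expect_equal(rmsdn_pressure(ref2 + 0.03, ref2, ctr), 1.5, tolerance = 1e-10)
  expect_error(rmsdn_pressure(sim, ref, c(5, 23, 23)), "outside")
  expect_error(rmsdn_pressure(sim, array(0, d), ctr), "normalizer")
})

test_that("temperature RMSD and its normalized variant follow Eq. 2", {
  d <- c(8, 8, 8)
  e <- array(2, d); e[4, 4, 4] <- 10
  s <- e + 0.5
  r <- rmsd_temperature(s, e)
  expect_equal(r$rmsd, 0.5, tolerance = 1e-12)
  expect_equal(r$rmsdn, 5, tolerance = 1e-12)   # normalized by peak rise 10
  reg <- list(3:5, 3:5, 3:5)
  expect_equal(rmsd_temperature(s, e, reg)$rmsd, 0.5, tolerance = 1e-12)
  expect_error(rmsd_temperature(s, array(0, d)), "normalizer")
})

test_that("FWHM of a 1 mm-sigma Gaussian is 2.3548 mm on every axis", {
  h <- 0.25
  x <- (seq_len(64) - 32.5) * h
  g <- exp(-outer(outer(x^2, x^2, `+`), x^2, `+`) / 2)  # sigma = 1 mm
  w <- fwhm(g, h)
  expect_equal(w, rep(2 * sqrt(2 * log(2)), 3), tolerance = h / 2.3548)
  # scale invariance
  expect_equal(fwhm(57.3 * g, h), w, tolerance = 1e-12)
  # impulse degenerates to one voxel width
  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 1
  expect_equal(fwhm(imp, 0.5), rep(0.5, 3), tolerance = 1e-12)
  # unbounded lobe is an error
  expect_error(fwhm(array(1, c(5, 5, 5)), 0.5), "unbounded")
})

test_that("peak difference is the documented asymmetric percentage", {
  a <- array(1, c(2, 2, 2)); b <- a
  expect_equal(peak_difference(a, b), 0)
  a[1] <- 1.09
  expect_equal(peak_difference(a, b), 9, tolerance = 1e-10)
  a1 <- array(1, c(2, 2, 2)); a2 <- array(2, c(2, 2, 2))
  expect_equal(peak_difference(a1, a2), 50)
  expect_equal(peak_difference(a2, a1), 100)
  expect_error(peak_difference(a1, array(0, c(2, 2, 2))), "zero")
})

test_that("center of thermal mass behaves like a weighted centroid", {
  d <- c(21, 21, 21); h <- 0.5
  x <- (seq_len(21) - 11) * h
  g <- 5 * exp(-outer(outer(x^2, x^2, `+`), x^2, `+`) / 2)
  ctr <- center_of_thermal_mass(g, h, 1.0, origin = c(-5, -5, -5))
  expect_equal(ctr, c(0, 0, 0), tolerance = 1e-6)
  # two equal masses -> midpoint
  f <- array(0, d); f[11, 11, 1] <- 2; f[11, 11, 21] <- 2
  ctr2 <- center_of_thermal_mass(f, h, 1.0, origin = c(0, 0, 0))
  expect_equal(ctr2, c(5, 5, 5))  # masses at z = 0 and 10 mm -> midpoint
  # translation equivariance by one voxel
  ft <- array(0, d); ft[11, 11, 2] <- 2; ft[11, 11, 21] <- 2
  expect_equal(center_of_thermal_mass(ft, h, 1.0)[3] -
               center_of_thermal_mass(f, h, 1.0)[3], h / 2)
  expect_error(center_of_thermal_mass(array(0, d), h), "empty mass")
  expect_equal(delta_cotm(c(0, 0, 0), c(3, 4, 0)), 5)
})

test_that("temperature curves follow the analytic uniform-heating slope", {
  d <- c(7, 7, 7)
  C <- GEL$density * GEL$specific_heat
  tm <- thermal_model(array(GEL$thermal_conductivity, d), array(C, d),
                      voxel_size = 0.5)
  Q0 <- 2e6
  Q <- structure(list(Q = array(Q0, d), voxel_size = 0.5, origin = c(0, 0, 0)),
                 class = "fus_q_volume")
  ser <- pennes_fdtd(tm, Q, sonication_protocol(5, 1, 0, 1), dt = 0.25)
  # uniform field: the peak voxel ties to a corner, so the mean cube clips
  expect_warning(cur <- temperature_curves(ser), "clipped")
  expect_equal(cur$peak, cur$mean, tolerance = 1e-12)    # uniform heating
  fit <- stats::coef(stats::lm(cur$peak ~ cur$times))
  expect_equal(unname(fit[2]), Q0 / C, tolerance = 1e-6)
  # cooling-only series: peak curve strictly decreasing
  x <- (seq_len(7) - 4) * 0.5
  g <- exp(-outer(outer(x^2, x^2, `+`), x^2, `+`))
  Qg <- structure(list(Q = 1e7 * g, voxel_size = 0.5, origin = c(0, 0, 0)),
                  class = "fus_q_volume")
  ser2 <- pennes_fdtd(tm, Qg, sonication_protocol(0.25, 1, 6, 1), dt = 0.25)
  cur2 <- temperature_curves(ser2)
  expect_true(all(diff(cur2$peak[-1]) < 0))
})
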