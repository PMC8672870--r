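gel_thermal <- function(d, h = 0.5) {
  C <- GEL$density * GEL$specific_heat
  thermal_model(array(GEL$thermal_conductivity, d), array(C, d),
                voxel_size = h)
}

test_that("power deposition implements Q = alpha |p|^2 / Z", {
  model <- uniform_model(c(4, 4, 4), GEL, 0.5, 940e3)
  p <- pressure_volume(array(1e6 + 0i, c(4, 4, 4)), 0.5, model$origin, 940e3)
  Q <- power_deposition(p, model)
  expect_equal(Q$Q[1, 1, 1], ALPHA_GEL_940 * 1e12 / Z_GEL, tolerance = 1e-12)
  expect_equal(Q$Q[1, 1, 1], 3.051e6, tolerance = 1e-4)
  # zero wherever attenuation is zero
  wmod <- water_model(4, 4, 0.5)
  Qw <- power_deposition(pressure_volume(array(1e6 + 0i, c(4, 4, 4)), 0.5,
                                         wmod$origin, 940e3), wmod)
  expect_true(all(Qw$Q == 0))
})

test_that("Q resampling conserves total deposited power", {
  set.seed(3)
  Q <- structure(list(Q = array(runif(16^3), c(16, 16, 16)), voxel_size = 0.25,
                      origin = c(0, 0, 0)), class = "fus_q_volume")
  Qc <- resample_power_deposition(Q, 2L)
  expect_equal(dim(Qc$Q), c(8, 8, 8))
  expect_equal(sum(Qc$Q) * Qc$voxel_size^3, sum(Q$Q) * Q$voxel_size^3,
               tolerance = 1e-12)
  expect_equal(Qc$voxel_size, 0.5)
})

test_that("the stability bound matches the closed form and guards the solver", {
  tm <- gel_thermal(c(8, 8, 8), 0.5)
  b <- stability_bound(tm)
  expect_equal(b, GEL$density * GEL$specific_heat * (0.5e-3)^2 /
                 (6 * GEL$thermal_conductivity), tolerance = 1e-12)
  expect_equal(b, 0.2828, tolerance = 1e-3)
  Q <- structure(list(Q = array(0, c(8, 8, 8)), voxel_size = 0.5,
                      origin = c(0, 0, 0)), class = "fus_q_volume")
  expect_error(pennes_fdtd(tm, Q, sonication_protocol(1, 1, 0, 1), dt = 0.3),
               "unstable")
})

test_that("uniform heating reproduces the analytic temperature rise exactly", {
  d <- c(6, 6, 6)
  tm <- gel_thermal(d)
  Q0 <- 1e6
  Q <- structure(list(Q = array(Q0, d), voxel_size = 0.5, origin = c(0, 0, 0)),
                 class = "fus_q_volume")
  # heating window not a multiple of dt: the fractional step must keep the
  # deposited energy exact
  ser <- pennes_fdtd(tm, Q, sonication_protocol(10, 1, 0, sample_interval = 10),
                     dt = 0.27)
  C <- GEL$density * GEL$specific_heat
  analytic <- Q0 * 10 / C
  expect_equal(analytic, 2.759, tolerance = 1e-3)
  final <- ser$fields[, , , dim(ser$fields)[4]]
  expect_equal(max(abs(final - analytic)) / analytic, 0, tolerance = 1e-3)
})

test_that("insulated boundaries conserve deposited energy after cooling", {
  d <- c(12, 12, 12); h <- 0.5
  tm <- gel_thermal(d, h)
  x <- (seq_len(12) - 6.5) * h
  g <- exp(-outer(outer(x^2, x^2, `+`), x^2, `+`) / 4)
  Q <- structure(list(Q = 5e6 * g, voxel_size = h, origin = c(0, 0, 0)),
                 class = "fus_q_volume")
  ser <- pennes_fdtd(tm, Q, sonication_protocol(20.84, 1, 15, 5), dt = 0.2)
  dV <- (h * 1e-3)^3
  C <- GEL$density * GEL$specific_heat
  deposited <- sum(Q$Q) * dV * 20.84
  final <- ser$fields[, , , dim(ser$fields)[4]]
  recovered <- sum(C * final) * dV
  expect_equal(recovered, deposited, tolerance = 0.005)
})

test_that("a cooling hotspot obeys the maximum principle", {
  d <- c(10, 10, 10); h <- 0.5
  tm <- gel_thermal(d, h)
  x <- (seq_len(10) - 5.5) * h
  g <- exp(-outer(outer(x^2, x^2, `+`), x^2, `+`) / 2)
  Q <- structure(list(Q = 1e7 * g, voxel_size = h, origin = c(0, 0, 0)),
                 class = "fus_q_volume")
  ser <- pennes_fdtd(tm, Q, sonication_protocol(0.2, 1, 10, 1), dt = 0.2)
  peaks <- apply(ser$fields, 4, max)
  expect_true(all(diff(peaks[-1]) < 0))   # strictly cooling after heating ends
  expect_true(all(ser$fields >= 0))
})

test_that("a symmetric source heats symmetrically", {
  d <- c(9, 9, 9); h <- 0.5
  tm <- gel_thermal(d, h)
  x <- (seq_len(9) - 5) * h
  g <- exp(-outer(outer(x^2, x^2, `+`), x^2, `+`) / 2)
  Q <- structure(list(Q = 1e7 * g, voxel_size = h, origin = c(0, 0, 0)),
                 class = "fus_q_volume")
  ser <- pennes_fdtd(tm, Q, sonication_protocol(3, 1, 0, 3), dt = 0.25)
  final <- ser$fields[, , , dim(ser$fields)[4]]
  expect_equal(final, final[9:1, , ], tolerance = 1e-12)
  expect_equal(final, aperm(final, c(2, 1, 3)), tolerance = 1e-12)
})

test_that("perfusion acts as a linear heat sink", {
  d <- c(6, 6, 6)
  C <- GEL$density * GEL$specific_heat
  w <- 2e4
  tm <- thermal_model(array(GEL$thermal_conductivity, d), array(C, d),
                      perfusion = array(w, d), voxel_size = 0.5)
  Q0 <- 1e6
  Q <- structure(list(Q = array(Q0, d), voxel_size = 0.5, origin = c(0, 0, 0)),
                 class = "fus_q_volume")
  ser <- pennes_fdtd(tm, Q, sonication_protocol(10, 1, 0, 1), dt = 0.05)
  # uniform problem: dT/dt = (Q - w T)/C -> T(t) = Q/w (1 - e^{-w t / C})
  t10 <- Q0 / w * (1 - exp(-w * 10 / C))
  expect_equal(ser$fields[3, 3, 3, dim(ser$fields)[4]], t10, tolerance = 5e-3)
})

test_that("models with missing thermal properties are rejected", {
  lm <- label_map(array(0L, c(4, 4, 4)), 0.5, c(0, 0, 0),
                  c("0" = "gelatin_30"))
  model <- assign_properties(lm, frequency = 940e3)
  expect_warning(tm <- thermal_model_from_labels(model), "without thermal")
  Q <- structure(list(Q = array(0, c(4, 4, 4)), voxel_size = 0.5,
                      origin = c(0, 0, 0)), class = "fus_q_volume")
  expect_error(pennes_fdtd(tm, Q, sonication_protocol(1, 1, 0, 1), dt = 0.1),
               "missing")
})

test_that("temperature series and protocol constructors validate inputs", {
  expect_error(sonication_protocol(-1, 1, 0, 1))
  expect_error(sonication_protocol(1, 1, 0, 0))
  expect_error(temperature_series(c(0, 0), array(0, c(2, 2, 2, 2)), 0.5))
  ser <- temperature_series(c(0, 1), array(0, c(2, 2, 2, 2)), 0.5)
  expect_s3_class(ser, "fus_temperature_series")
})
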