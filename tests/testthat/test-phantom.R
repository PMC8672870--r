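test_that("inclusion specification is validated", {
  expect_error(inclusion("sphere", c(0, 0), 4), "length")
  expect_error(inclusion("sphere", c(0, 0, 10), -1), "semi_axes")
  inc <- inclusion("sphere", c(0, 0, 10), 4)
  expect_equal(inc$semi_axes, c(4, 4, 4))
})

test_that("rasterized inclusion volume converges to the analytic volume", {
  inc <- inclusion("sphere", c(0, 0, 15), 4)
  vol_true <- 4 / 3 * pi * 4^3
  err <- vapply(c(1, 0.5), function(h) {
    lm <- build_cylinder_phantom(30, 30, inclusions = list(inc), voxel_size = h)
    abs(sum(lm$labels == 2L) * h^3 - vol_true) / vol_true
  }, 0)
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.02)
})

test_that("cylinder phantom labels host, surround, and inclusions correctly", {
  lm <- build_cylinder_phantom(20, 10, voxel_size = 1, margin = 3)
  expect_s3_class(lm, "fus_label_map")
  expect_setequal(unique(as.vector(lm$labels)), c(0L, 1L))
  ax <- grid_axes(lm)
  # a voxel on the axis is host; a far transverse corner is surround
  i0 <- which.min(abs(ax$x)); k0 <- which.min(abs(ax$z - 5))
  expect_equal(lm$labels[i0, i0, k0], 1L)
  expect_equal(lm$labels[1, 1, k0], 0L)
  # host cylinder volume close to analytic
  expect_equal(sum(lm$labels == 1L) * 1, pi * 10^2 * 10, tolerance = 0.05)
})

test_that("inclusions poking out of the host are clipped with a warning", {
  # sticks out of the cylinder side wall (|x| up to 17 > radius 15); the
  # 2 mm grid margin keeps voxels outside the host on the grid, so the
  # protruding part must be clipped
  inc <- inclusion("sphere", c(12, 0, 15), 5)
  expect_warning(lm <- build_cylinder_phantom(30, 30, inclusions = list(inc),
                                              voxel_size = 1), "clipped")
  # every surviving inclusion voxel lies inside the host cylinder
  ax <- grid_axes(lm)
  idx <- which(lm$labels == 2L, arr.ind = TRUE)
  expect_gt(nrow(idx), 0)
  expect_true(all(ax$x[idx[, 1]]^2 + ax$y[idx[, 2]]^2 <= 15^2 + 1e-9))
  expect_true(all(ax$z[idx[, 3]] >= 0 & ax$z[idx[, 3]] <= 30))
})

test_that("assign_properties produces the per-material grids", {
  inc <- inclusion("sphere", c(0, 0, 15), 5)
  lm <- build_cylinder_phantom(30, 30, inclusions = list(inc), voxel_size = 1)
  mod <- assign_properties(lm, frequency = 940e3)
  expect_equal(mod$speed[lm$labels == 1L][1], 1578.5)
  expect_equal(mod$speed[lm$labels == 2L][1], 1462)
  expect_equal(mod$attenuation[lm$labels == 1L][1], ALPHA_GEL_940)
  expect_equal(mod$density[lm$labels == 0L][1], 998)
  expect_equal(mod$frequency, 940e3)
  expect_error(assign_properties(lm, table = default_material_table()["water"],
                                 frequency = 940e3), "unknown material")
})

test_that("property grids are invariant to label renumbering", {
  inc <- inclusion("sphere", c(0, 0, 15), 5)
  lm <- build_cylinder_phantom(30, 30, inclusions = list(inc), voxel_size = 1)
  perm <- lm
  perm$labels <- array(c(5L, 9L, 7L)[lm$labels + 1L], dim(lm$labels))
  perm$label_key <- stats::setNames(lm$label_key, c("5", "9", "7"))
  a <- assign_properties(lm, frequency = 940e3)
  b <- assign_properties(perm, frequency = 940e3)
  expect_identical(a$speed, b$speed)
  expect_identical(a$attenuation, b$attenuation)
  expect_identical(a$density, b$density)
})

test_that("label_map refuses labels missing from the key", {
  expect_error(label_map(array(3L, c(2, 2, 2)), 1, c(0, 0, 0),
                         c("0" = "water")), "absent from label_key")
})

test_that("phantom presets are seed-deterministic and seed-sensitive", {
  a <- phantom_preset("p-type-het", voxel_size = 1, seed = 4)
  b <- phantom_preset("p-type-het", voxel_size = 1, seed = 4)
  c <- phantom_preset("p-type-het", voxel_size = 1, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$labels, c$labels))
  expect_equal(sort(unique(as.vector(a$labels))), 0:4)  # host + 3 inclusions
  hom <- phantom_preset("p-type-hom", milk = 50, voxel_size = 1)
  expect_equal(unname(hom$label_key["1"]), "gelatin_50")
})

test_that("uniform_model covers the grid with one material", {
  m <- uniform_model(c(4, 5, 6), default_material_table()$water, 0.5, 1e6)
  expect_equal(dim(m$speed), c(4, 5, 6))
  expect_true(all(m$speed == 1482))
  expect_true(all(m$attenuation == 0))
})
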