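#' Reduced cross-validation scenario: split-step HAS vs full-wave reference
#'
#' A compact heterogeneous benchmark used to quantify the accuracy of the
#' one-way split-step propagator against the independent full-wave solver:
#' a 30 x 30 x 40 mm domain at 0.25 mm, water standoff 0-5 mm, a uniform
#' 70%-milk gelatin slab from 5 to 35 mm, and one canola-oil sphere of
#' 8-10 mm diameter in the pre-focal half of the slab. The sphere diameter
#' and center jitter are drawn from a seeded generator; everything else is
#' fixed. Attenuation is scaled linearly from the 1 MHz table values to the
#' 940 kHz operating frequency by [assign_properties()].
#'
#' @param seed integer; all randomness (inclusion size/position) derives from
#'   it via an isolated substream.
#' @param voxel_size mm (default 0.25).
#' @return A [label_map()] (water = 0, gelatin_70 = 1, canola_oil = 2).
#' @export
crossval_phantom <- function(seed, voxel_size = 0.25) {
  rng <- local_rng(substream_seed(seed, "crossval-phantom"))
  radius <- rng$runif(1, 4, 5)                       # 8-10 mm diameter
  ctr <- c(rng$runif(1, -1.5, 1.5), rng$runif(1, -1.5, 1.5),
           rng$runif(1, 13, 17))
  h <- voxel_size
  n_xy <- as.integer(round(30 / h))
  n_z <- as.integer(round(40 / h))
  origin <- c(-(n_xy - 1) / 2 * h, -(n_xy - 1) / 2 * h, h / 2)
  xs <- origin[1] + (seq_len(n_xy) - 1) * h
  zs <- origin[3] + (seq_len(n_z) - 1) * h

  labels <- array(0L, c(n_xy, n_xy, n_z))
  in_slab <- zs >= 5 & zs <= 35
  labels[, , in_slab] <- 1L
  u2 <- outer((xs - ctr[1])^2, (xs - ctr[2])^2, `+`)
  inside <- outer(u2, (zs - ctr[3])^2, `+`) <= radius^2
  labels[inside] <- 2L
  label_map(labels, h, origin,
            c("0" = "water", "1" = "gelatin_70", "2" = "canola_oil"))
}

#' Analytic focused source plane
#'
#' A Gaussian-apodized spherically converging wavefront: amplitude
#' `exp(-r^2 / beam_width^2)` with a raised-cosine edge roll-off, phase
#' `+k (sqrt(r^2 + focus_z^2) - focus_z)` so the field converges to
#' `(0, 0, focus_z)` (repo phasor convention `e^{+j w t}`, forward
#' `e^{-j k z}`). Used to drive the HAS and full-wave solvers with an
#' identical input in cross-validation; any [pressure_plane()] (e.g. from
#' [rayleigh_sommerfeld()]) can be substituted.
#'
#' @param n transverse grid size (plane is n x n).
#' @param pixel_size mm.
#' @param frequency Hz.
#' @param focus_z focal distance from the plane, mm.
#' @param speed m/s of the medium at the plane.
#' @param beam_width Gaussian 1/e amplitude radius, mm.
#' @param peak peak amplitude, Pa.
#' @param taper_width raised-cosine roll-off width, pixels.
#' @return A [pressure_plane()] at z = 0.
#' @export
focused_source_plane <- function(n, pixel_size, frequency, focus_z, speed,
                                 beam_width = 6, peak = 1, taper_width = 10) {
  stopifnot(focus_z > 0, beam_width > 0, speed > 0)
  x <- (seq_len(n) - (n + 1) / 2) * pixel_size
  r2 <- outer(x^2, x^2, `+`)
  k <- 2 * pi * frequency / speed / 1e3          # rad/mm
  apod <- peak * exp(-r2 / beam_width^2) *
    outer(cosine_edge(n, taper_width), cosine_edge(n, taper_width))
  pressure_plane(apod * exp(1i * k * (sqrt(r2 + focus_z^2) - focus_z)),
                 pixel_size, 0, frequency)
}

#' Normalized RMS difference between HAS and the full-wave reference
#'
#' Runs the complete cross-validation: builds the seeded phantom
#' ([crossval_phantom()]), drives [has_propagate()] and
#' [fullwave_steady_state()] with the identical focused source plane, and
#' evaluates [rmsdn_pressure()] over a `(2 half_width + 1)^3` region centered
#' on the actual focal peak -- the global maximum voxel of the full-wave
#' reference pattern (the sound-speed contrast of the slab shifts the focus
#' up-beam of the geometric focus, so centering there would miss the focal
#' lobe) -- with the full-wave pattern as the reference (its global maximum
#' is the normalizer; neither pattern is self-normalized).
#'
#' @param seed integer seed for the phantom generator.
#' @param half_width comparison region half-width in voxels (default 20,
#'   i.e. 41^3).
#' @param verbose print full-wave convergence progress.
#' @return list with `value` (RMSDn, percent), `n` (number of compared
#'   voxels), `center` (region center voxel), `peak_difference` (percent),
#'   `fullwave_iterations`, `fullwave_residual`.
#' @export
crossval_rmsdn <- function(seed, half_width = 20L, verbose = FALSE) {
  frequency <- 940e3
  lmap <- crossval_phantom(seed)
  model <- assign_properties(lmap, frequency = frequency)
  water <- default_material_table()$water
  src <- focused_source_plane(dim(model$speed)[1], model$voxel_size, frequency,
                              focus_z = 30, speed = water$speed_of_sound)
  # the source plane carries its own edge taper; disable the propagator's so
  # both solvers receive the identical field
  has <- has_propagate(model, src, propagation_settings(edge_taper_width = 0))
  fw <- fullwave_steady_state(model, src, verbose = verbose)

  # region centered on the focal peak of the reference pattern (ties broken
  # by lowest linear index), clamped so the region fits the grid
  d <- dim(fw$values)
  center <- arrayInd(which.max(Mod(fw$values)), d)[1, ]
  center <- pmin(pmax(center, half_width + 1L), d - half_width)
  list(value = rmsdn_pressure(has, fw, center, half_width),
       n = (2L * half_width + 1L)^3,
       center = center,
       peak_difference = peak_difference(has, fw),
       fullwave_iterations = attr(fw, "iterations"),
       fullwave_residual = attr(fw, "residual"))
}
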