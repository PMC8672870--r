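#' Propagation settings for the hybrid angular spectrum solver
#'
#' @param pad_fraction transverse zero-padding per side as a fraction of the
#'   grid size (suppresses FFT wrap-around).
#' @param evanescent `"decay"` (default) or `"zero"`.
#' @param reflection_passes number of interface reflection passes to add to
#'   the forward field (0 = forward only; default 2: one backward and one
#'   re-reflected forward pass).
#' @param edge_taper_width raised-cosine roll-off width in voxels applied to
#'   the source plane edges.
#' @return A `fus_prop_settings`.
#' @export
propagation_settings <- function(pad_fraction = 0.25,
                                 evanescent = c("decay", "zero"),
                                 reflection_passes = 2L,
                                 edge_taper_width = 16L) {
  evanescent <- match.arg(evanescent)
  stopifnot(pad_fraction >= 0, reflection_passes >= 0)
  structure(list(pad_fraction = pad_fraction, evanescent = evanescent,
                 reflection_passes = as.integer(reflection_passes),
                 edge_taper_width = as.integer(edge_taper_width)),
            class = "fus_prop_settings")
}

# Internal engine shared by the forward pass and the reflection sweeps.
# Holds the padded working grid, spectral kt^2 grid, and the per-plane
# heterogeneity factors of the model.
has_engine <- function(model, plane, settings) {
  if (abs(model$frequency - plane$frequency) > 1e-6 * model$frequency)
    stop("configuration error: source plane frequency (", plane$frequency,
         " Hz) does not match model frequency (", model$frequency, " Hz)")
  d <- dim(model$speed)
  if (!all(dim(plane$values) == d[1:2]))
    stop("configuration error: source plane grid (", paste(dim(plane$values), collapse = "x"),
         ") does not match model transverse grid (", paste(d[1:2], collapse = "x"), ")")
  if (abs(plane$pixel_size - model$voxel_size) > 1e-9)
    stop("configuration error: source pixel size != model voxel size")
  front_face <- model$origin[3] - model$voxel_size / 2
  if (abs(plane$plane_z - front_face) > 1e-6)
    stop("configuration error: source plane z = ", plane$plane_z,
         " mm, model front face at ", front_face, " mm")
  if (any(model$speed <= 0) || any(!is.finite(model$speed)))
    stop("invalid model: non-positive speed of sound")

  npad <- vapply(d[1:2], function(n)
    next_fast_size(as.integer(ceiling(n * (1 + 2 * settings$pad_fraction)))), 1L)
  pm <- pad_matrix(matrix(0 + 0i, d[1], d[2]), npad)
  list(
    dims = d, npad = npad, ix = pm$ix, iy = pm$iy,
    kt2 = kt2_grid(npad[1], npad[2], model$voxel_size * 1e-3),
    dz_m = model$voxel_size * 1e-3,
    omega = 2 * pi * model$frequency
  )
}

# One split-step through (a fraction `frac` of) slab i of the model, on the
# padded field.
# (a) space-domain: voxel-specific phase deviation from the planar-average
#     wavenumber plus voxel-wise attenuation; (b) spectral: lossless
#     angular-spectrum advance by frac*dz using the planar-averaged wavenumber.
# Marching a slab as two half-steps records the field at the voxel-center
# plane (the repo-wide grid registration) halfway through.
has_step <- function(field, eng, model, i, direction = 1,
                     evanescent = "decay", frac = 1) {
  kplane <- eng$omega / model$speed[, , i]
  kbar <- mean(kplane)
  dz <- frac * eng$dz_m
  fac_space <- exp(complex(real = -model$attenuation[, , i] * dz,
                           imaginary = -(kplane - kbar) * dz))
  field[eng$ix, eng$iy] <- field[eng$ix, eng$iy] * fac_space
  fac_spec <- spectral_factor(eng$kt2, kbar, direction * dz, evanescent)
  stats::fft(stats::fft(field) * fac_spec, inverse = TRUE) / prod(eng$npad)
}

#' Hybrid angular spectrum propagation through a heterogeneous voxel model
#'
#' Split-step propagation of a complex source pressure plane through a
#' heterogeneous voxel model, plane by plane along z. For each transverse
#' slab the step is (a) a space-domain multiplication by the voxel-specific
#' phase deviation from the plane-averaged wavenumber together with the
#' voxel-wise attenuation, and (b) a spectral-domain angular-spectrum advance
#' over one voxel using the plane-averaged wavenumber. For a homogeneous
#' model the scheme reduces exactly to the traditional angular spectrum
#' method. Each slab is marched as two half-steps so that plane i of the
#' result is the field at the *center* of voxel slab i, i.e. at
#' `z = origin[3] + (i - 1) * voxel_size` — the same registration as every
#' other volume in the package.
#'
#' With `reflection_passes >= 1`, normal-incidence reflections
#' `R = (Z2 - Z1)/(Z2 + Z1)` are generated at every axial impedance
#' interface from the forward field, back-propagated with the same split-step
#' scheme, and (with 2 passes) re-reflected forward; all passes are summed
#' coherently. In a uniform-impedance model the correction is identically
#' zero.
#'
#' @param model a `fus_voxel_model` (see [assign_properties()]).
#' @param source a [pressure_plane()] registered to the model front face.
#' @param settings a [propagation_settings()].
#' @return A [pressure_volume()] matching the model grid.
#' @export
has_propagate <- function(model, source, settings = propagation_settings()) {
  stopifnot(inherits(model, "fus_voxel_model"),
            inherits(source, "fus_pressure_plane"))
  eng <- has_engine(model, source, settings)
  d <- eng$dims

  v <- source$values
  if (settings$edge_taper_width > 0)
    v <- v * outer(cosine_edge(d[1], settings$edge_taper_width),
                   cosine_edge(d[2], settings$edge_taper_width))
  field <- pad_matrix(v, eng$npad)$field

  fwd <- array(0 + 0i, d)
  need_face <- settings$reflection_passes >= 1L
  # interface-registered forward field (back face of slab i), needed only to
  # seed the reflection sweeps
  fwd_face <- if (need_face) array(0 + 0i, d) else NULL
  for (i in seq_len(d[3])) {
    field <- has_step(field, eng, model, i, 1, settings$evanescent, frac = 0.5)
    fwd[, , i] <- field[eng$ix, eng$iy]
    field <- has_step(field, eng, model, i, 1, settings$evanescent, frac = 0.5)
    if (need_face) fwd_face[, , i] <- field[eng$ix, eng$iy]
  }
  out <- fwd
  if (settings$reflection_passes >= 1L) {
    refl <- reflection_fields(model, fwd_face, eng, settings)
    out <- out + refl$backward
    if (settings$reflection_passes >= 2L) out <- out + refl$forward2
  }
  pressure_volume(out, model$voxel_size, model$origin, model$frequency)
}

# Backward reflection sweep and forward re-reflection sweep.
# Interface j sits between slab j and slab j+1, i.e. at the back face of
# slab j; `fwd_face` is the forward field registered at those back faces.
# Outputs are registered at voxel centers, like the forward field.
reflection_fields <- function(model, fwd_face, eng, settings) {
  d <- eng$dims
  Z <- model$density * model$speed
  backward <- array(0 + 0i, d)
  forward2 <- array(0 + 0i, d)
  nz <- d[3]
  if (nz < 2) return(list(backward = backward, forward2 = forward2))

  # R_j(x,y) for the forward wave crossing interface j
  Rj <- (Z[, , 2:nz, drop = FALSE] - Z[, , 1:(nz - 1), drop = FALSE]) /
        (Z[, , 2:nz, drop = FALSE] + Z[, , 1:(nz - 1), drop = FALSE])
  if (all(Rj == 0)) return(list(backward = backward, forward2 = forward2))

  # backward pass: marching down from interface nz-1, the wave arriving at
  # interface j from deeper interfaces (b_face, the incident wave for
  # re-reflection) gains the locally born reflection R_j * fwd_face_j, then
  # crosses slab j (recorded at its center halfway through).
  # a backward-traveling wave advances by +dz in its own frame, so the step
  # operator is the same as for the forward wave (mirror symmetry in z)
  b <- pad_matrix(matrix(0 + 0i, d[1], d[2]), eng$npad)$field
  b_face <- array(0 + 0i, c(d[1], d[2], nz - 1))
  for (j in (nz - 1):1) {
    b_face[, , j] <- b[eng$ix, eng$iy]
    b[eng$ix, eng$iy] <- b[eng$ix, eng$iy] + Rj[, , j] * fwd_face[, , j]
    b <- has_step(b, eng, model, j, 1, settings$evanescent, frac = 0.5)
    backward[, , j] <- b[eng$ix, eng$iy]
    b <- has_step(b, eng, model, j, 1, settings$evanescent, frac = 0.5)
  }
  # forward re-reflection: the backward wave arriving at interface i-1 from
  # deeper interfaces reflects with -R_{i-1} back into the forward direction
  # (the wave born at interface i-1 itself never re-crosses it)
  f <- pad_matrix(matrix(0 + 0i, d[1], d[2]), eng$npad)$field
  for (i in 2:nz) {
    f[eng$ix, eng$iy] <- f[eng$ix, eng$iy] - Rj[, , i - 1] * b_face[, , i - 1]
    f <- has_step(f, eng, model, i, 1, settings$evanescent, frac = 0.5)
    forward2[, , i] <- f[eng$ix, eng$iy]
    f <- has_step(f, eng, model, i, 1, settings$evanescent, frac = 0.5)
  }
  list(backward = backward, forward2 = forward2)
}

#' Normal-incidence interface coefficients
#'
#' Pressure reflection and transmission coefficients at a planar interface,
#' `R = (Z2 - Z1)/(Z2 + Z1)`, `T = 2 Z2/(Z2 + Z1)`; they satisfy the energy
#' identity `R^2 + (Z1/Z2) T^2 = 1`.
#'
#' @param Z1,Z2 acoustic impedances (Rayl) of the incidence and transmission
#'   media.
#' @return list with `R` and `T`.
#' @export
interface_coefficients <- function(Z1, Z2) {
  list(R = (Z2 - Z1) / (Z2 + Z1), T = 2 * Z2 / (Z2 + Z1))
}
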