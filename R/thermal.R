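#' Deposited acoustic power density
#'
#' Converts a steady-state pressure magnitude field to the volumetric heat
#' source of the bioheat equation, `Q = alpha |p|^2 / Z` with `alpha` in Np/m,
#' `Z = rho c` in Rayl and `|p|` the peak phasor amplitude.
#'
#' @param pressure a [pressure_volume()].
#' @param model the `fus_voxel_model` it was computed on (same grid).
#' @return A `fus_q_volume` with `Q` (W/m^3), `voxel_size`, `origin`.
#' @export
power_deposition <- function(pressure, model) {
  stopifnot(inherits(pressure, "fus_pressure_volume"),
            inherits(model, "fus_voxel_model"))
  if (!identical(dim(pressure$values), dim(model$speed)))
    stop("alignment error: pressure and model grids differ")
  Q <- model$attenuation * Mod(pressure$values)^2 / (model$density * model$speed)
  structure(list(Q = Q, voxel_size = pressure$voxel_size,
                 origin = pressure$origin),
            class = "fus_q_volume")
}

#' Conservative downsampling of a power deposition volume
#'
#' Volume-weighted block averaging from a finer acoustic grid (e.g. 0.25 mm)
#' to a coarser thermal grid (e.g. 0.5 mm); total deposited power
#' `sum(Q) dV` is conserved. The grid ratio must be a positive integer and
#' divide the grid dimensions (trailing voxels are dropped with a warning if
#' not).
#'
#' @param q a `fus_q_volume`.
#' @param factor integer downsampling factor per axis.
#' @return A coarser `fus_q_volume`.
#' @export
resample_power_deposition <- function(q, factor = 2L) {
  factor <- as.integer(factor)
  stopifnot(inherits(q, "fus_q_volume"), factor >= 1L)
  if (factor == 1L) return(q)
  d <- dim(q$Q)
  dn <- d %/% factor
  if (any(d %% factor != 0L)) {
    warning("grid not divisible by ", factor, "; trailing voxels dropped")
    q$Q <- q$Q[seq_len(dn[1] * factor), seq_len(dn[2] * factor),
               seq_len(dn[3] * factor), drop = FALSE]
  }
  a <- array(q$Q, c(factor, dn[1], factor, dn[2], factor, dn[3]))
  Qc <- apply(a, c(2, 4, 6), mean)
  structure(list(Q = Qc, voxel_size = q$voxel_size * factor,
                 origin = q$origin + (factor - 1) / 2 * q$voxel_size),
            class = "fus_q_volume")
}

#' Thermal model grids
#'
#' @param conductivity 3D grid, W/m/degC, > 0.
#' @param volumetric_heat_capacity 3D grid `rho * c_p`, J/m^3/degC, > 0.
#' @param perfusion 3D grid, W/m^3/degC, >= 0 (0 for phantoms).
#' @param voxel_size mm.
#' @param origin mm.
#' @return A `fus_thermal_model`.
#' @export
thermal_model <- function(conductivity, volumetric_heat_capacity,
                          perfusion = NULL, voxel_size, origin = c(0, 0, 0)) {
  d <- dim(conductivity)
  stopifnot(length(d) == 3L, identical(dim(volumetric_heat_capacity), d))
  if (is.null(perfusion)) perfusion <- array(0, d)
  ok <- function(x) all(is.na(x) | x > 0)
  if (!ok(conductivity) || !ok(volumetric_heat_capacity))
    stop("conductivity and heat capacity must be > 0")
  if (any(perfusion < 0, na.rm = TRUE)) stop("perfusion must be >= 0")
  structure(list(conductivity = conductivity,
                 volumetric_heat_capacity = volumetric_heat_capacity,
                 perfusion = perfusion, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "fus_thermal_model")
}

#' Thermal model from a voxel model's labels and a material table
#'
#' Voxels whose material lacks thermal properties get `NA` grids here and are
#' rejected by [pennes_fdtd()]; this mirrors the acoustic-only materials in
#' the property table.
#'
#' @param model a `fus_voxel_model` (labels retained by [assign_properties()]).
#' @param table named list of [material()] objects.
#' @return A [thermal_model()] on the model grid.
#' @export
thermal_model_from_labels <- function(model, table = default_material_table()) {
  stopifnot(inherits(model, "fus_voxel_model"))
  present <- sort(unique(as.vector(model$labels)))
  mats <- model$label_key[as.character(present)]
  k_by <- vapply(mats, function(m) table[[m]]$thermal_conductivity, 0)
  c_by <- vapply(mats, function(m)
    table[[m]]$specific_heat * table[[m]]$density, 0)
  if (any(is.na(k_by)))
    warning("materials without thermal properties: ",
            paste(mats[is.na(k_by)], collapse = ", "),
            " (model unusable for thermal simulation)")
  idx <- match(model$labels, present)
  d <- dim(model$labels)
  thermal_model(array(k_by[idx], d), array(c_by[idx], d),
                voxel_size = model$voxel_size, origin = model$origin)
}

#' Explicit-stability time-step bound for the bioheat FDTD scheme
#'
#' Returns `min over voxels of (rho c_p) dx^2 / (6 k)`, the forward-Euler
#' stability limit of the 7-point conduction stencil. A vanishing-conductivity
#' voxel would give an infinite bound; the result is capped at 1e6 s with a
#' warning.
#'
#' @param thermal a [thermal_model()].
#' @param grid optional voxel size override, mm.
#' @return Seconds.
#' @export
stability_bound <- function(thermal, grid = thermal$voxel_size) {
  dx <- grid * 1e-3
  b <- min(thermal$volumetric_heat_capacity * dx^2 / (6 * thermal$conductivity),
           na.rm = TRUE)
  if (!is.finite(b) || b > 1e6) {
    warning("stability bound unbounded (near-zero conductivity); capped at 1e6 s")
    b <- 1e6
  }
  b
}

#' Sonication protocol
#'
#' @param heat_duration s of continuous sonication.
#' @param acoustic_power W (used by the pipeline to scale Q linearly from the
#'   power the pressure solution was computed at).
#' @param post_cool s of cooling simulated after the sonication.
#' @param sample_interval s between stored temperature frames (>= solver dt).
#' @return A `fus_protocol`.
#' @export
sonication_protocol <- function(heat_duration = 20.84, acoustic_power = 50.1,
                                post_cool = 20, sample_interval = 1) {
  stopifnot(heat_duration >= 0, acoustic_power >= 0, post_cool >= 0,
            sample_interval > 0)
  structure(list(heat_duration = heat_duration, acoustic_power = acoustic_power,
                 post_cool = post_cool, sample_interval = sample_interval),
            class = "fus_protocol")
}

#' Temperature-rise series
#'
#' @param times s, strictly increasing, starting at 0.
#' @param fields 4D array (nx, ny, nz, length(times)) of temperature rise, degC.
#' @param voxel_size mm.
#' @param origin mm.
#' @return A `fus_temperature_series`.
#' @export
temperature_series <- function(times, fields, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(length(dim(fields)) == 4L, dim(fields)[4] == length(times),
            all(diff(times) > 0))
  structure(list(times = as.numeric(times), fields = fields,
                 voxel_size = as.numeric(voxel_size), origin = as.numeric(origin)),
            class = "fus_temperature_series")
}

#' Explicit finite-difference solution of the Pennes bioheat equation
#'
#' Forward-Euler update of `rho c_p dT/dt = div(k grad T) + Q - w (T - T0)`
#' on the thermal grid with harmonic-mean face conductivities at material
#' interfaces, zero-flux (mirror) boundaries, and a uniform initial
#' temperature rise of 0. `Q` is active for `heat_duration` and then zero;
#' the step straddling the end of heating applies `Q` for exactly the
#' remaining fraction, so deposited energy is `integral(Q dV) x
#' heat_duration` to machine precision. Repeated sonications with cooling
#' intervals are simulated by passing a list of protocols; temperature
#' carries over between them.
#'
#' @param thermal a [thermal_model()].
#' @param Q a `fus_q_volume` on the same grid (resample first; see
#'   [resample_power_deposition()]).
#' @param protocol a [sonication_protocol()] or list of them (sequential
#'   sonications).
#' @param dt solver time step, s; refused if above [stability_bound()].
#' @param safety stability safety factor (bound divided by `safety`).
#' @return A [temperature_series()] sampled every `sample_interval` (frame 1
#'   is t = 0).
#' @export
pennes_fdtd <- function(thermal, Q, protocol, dt = 0.1, safety = 1) {
  stopifnot(inherits(thermal, "fus_thermal_model"),
            inherits(Q, "fus_q_volume"))
  if (!identical(dim(Q$Q), dim(thermal$conductivity)))
    stop("alignment error: Q grid does not match thermal grid; resample first")
  if (abs(Q$voxel_size - thermal$voxel_size) > 1e-9)
    stop("alignment error: Q voxel size does not match thermal grid")
  if (anyNA(thermal$conductivity) || anyNA(thermal$volumetric_heat_capacity))
    stop("configuration error: thermal properties missing for some voxels")
  bound <- stability_bound(thermal) / max(1, safety)
  if (dt > bound * (1 + 1e-12))
    stop(sprintf("unstable time step: dt = %g s exceeds the explicit bound %g s",
                 dt, bound))
  if (inherits(protocol, "fus_protocol")) protocol <- list(protocol)
  sample_interval <- protocol[[1]]$sample_interval
  nsub <- max(1L, as.integer(round(sample_interval / dt)))

  d <- dim(Q$Q)
  kx <- thermal$conductivity
  C <- thermal$volumetric_heat_capacity
  w <- thermal$perfusion
  dx <- thermal$voxel_size * 1e-3
  # harmonic-mean face conductivities, one set per axis
  hmean <- function(a, b) 2 * a * b / (a + b)
  kfx <- hmean(kx[-d[1], , , drop = FALSE], kx[-1, , , drop = FALSE])
  kfy <- hmean(kx[, -d[2], , drop = FALSE], kx[, -1, , drop = FALSE])
  kfz <- hmean(kx[, , -d[3], drop = FALSE], kx[, , -1, drop = FALSE])
  lap <- function(T) {
    L <- array(0, d)
    Dx <- kfx * (T[-1, , , drop = FALSE] - T[-d[1], , , drop = FALSE])
    L[-d[1], , ] <- L[-d[1], , , drop = FALSE] + Dx
    L[-1, , ] <- L[-1, , , drop = FALSE] - Dx
    Dy <- kfy * (T[, -1, , drop = FALSE] - T[, -d[2], , drop = FALSE])
    L[, -d[2], ] <- L[, -d[2], , drop = FALSE] + Dy
    L[, -1, ] <- L[, -1, , drop = FALSE] - Dy
    Dz <- kfz * (T[, , -1, drop = FALSE] - T[, , -d[3], drop = FALSE])
    L[, , -d[3]] <- L[, , -d[3], drop = FALSE] + Dz
    L[, , -1] <- L[, , -1, drop = FALSE] - Dz
    L / dx^2
  }

  T <- array(0, d)
  frames <- list(T)
  times <- 0
  t <- 0
  for (p in protocol) {
    seg_end_heat <- t + p$heat_duration
    seg_end <- seg_end_heat + p$post_cool
    istep <- 0L
    while (t < seg_end - 1e-12) {
      step_end <- min(t + dt, seg_end)
      h <- step_end - t
      # fraction of this step inside the heating window
      heat_frac <- max(0, min(step_end, seg_end_heat) - t) / h
      src <- if (heat_frac > 0) heat_frac * Q$Q else 0
      T <- T + (h / C) * (lap(T) + src - w * T)
      t <- step_end
      istep <- istep + 1L
      if (istep %% nsub == 0L || t >= seg_end - 1e-12) {
        frames[[length(frames) + 1L]] <- T
        times <- c(times, t)
      }
    }
  }
  keep <- !duplicated(times)
  fields <- array(unlist(frames[keep], use.names = FALSE), c(d, sum(keep)))
  temperature_series(times[keep], fields, thermal$voxel_size, thermal$origin)
}

#' @export
print.fus_temperature_series <- function(x, ...) {
  d <- dim(x$fields)
  cat(sprintf("<temperature series: %d frames over %.1f s, grid %d x %d x %d @ %.3g mm, peak rise %.2f degC>\n",
              d[4], max(x$times), d[1], d[2], d[3], x$voxel_size,
              max(x$fields)))
  invisible(x)
}
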