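#' Pipeline configuration
#'
#' Collects all knobs of the end-to-end simulation in one validated object.
#' Every random choice in a run (inclusion placement, array layout) derives
#' from `seed` through named substreams, so a configuration is fully
#' reproducible from this object alone.
#'
#' @param seed master integer seed.
#' @param frequency operating frequency, Hz.
#' @param phantom either a [label_map()] or a list of [phantom_preset()]
#'   arguments (fields `preset`, `milk`, `voxel_size`, `front_z`).
#' @param array_spec [make_array()] spec list; `layout_seed` defaults to a
#'   substream of `seed`.
#' @param target focus point, mm (default the geometric focus).
#' @param protocol a [sonication_protocol()] or list of them.
#' @param settings a [propagation_settings()].
#' @param thermal_factor integer acoustic-to-thermal grid ratio (default 2,
#'   e.g. 0.25 mm to 0.5 mm).
#' @param dt thermal solver step, s.
#' @param reference `"none"`, `"angular_spectrum"` (homogeneous water
#'   reference on the same grid) or `"fullwave"` (heterogeneous full-wave
#'   reference; expensive).
#' @param material_table named list of [material()] objects.
#' @return A `fus_run_config`.
#' @export
run_config <- function(seed = 1L,
                       frequency = 940e3,
                       phantom = list(preset = "p-type-het", milk = 70,
                                      voxel_size = 0.25, front_z = 70),
                       array_spec = list(),
                       target = NULL,
                       protocol = sonication_protocol(),
                       settings = propagation_settings(),
                       thermal_factor = 2L,
                       dt = 0.1,
                       reference = c("none", "angular_spectrum", "fullwave"),
                       material_table = default_material_table()) {
  reference <- match.arg(reference)
  stopifnot(is.numeric(seed), length(seed) == 1L, frequency > 0,
            thermal_factor >= 1L, dt > 0)
  if (is.null(array_spec$layout_seed))
    array_spec$layout_seed <- substream_seed(seed, "array-layout")
  if (is.null(array_spec$frequency_Hz)) array_spec$frequency_Hz <- frequency
  if (inherits(protocol, "fus_protocol")) protocol <- list(protocol)
  stopifnot(all(vapply(protocol, inherits, TRUE, "fus_protocol")))
  structure(list(seed = as.integer(seed), frequency = frequency,
                 phantom = phantom, array_spec = array_spec, target = target,
                 protocol = protocol, settings = settings,
                 thermal_factor = as.integer(thermal_factor), dt = dt,
                 reference = reference, material_table = material_table),
            class = "fus_run_config")
}

#' Run the end-to-end simulation pipeline
#'
#' Executes the full chain: phantom rasterization, material assignment,
#' phased-array construction and focusing, Rayleigh-Sommerfeld evaluation of
#' the source plane at the model front face, power scaling, split-step HAS
#' propagation (with reflection passes), power deposition `Q = alpha |p|^2 / Z`,
#' conservative resampling to the thermal grid, explicit Pennes bioheat
#' solution over the sonication protocol, and summary metrics. If
#' `config$reference` is set, a reference pressure solution is computed on
#' the same grid from the identical source plane and compared with
#' [comparison_report()].
#'
#' @param config a [run_config()].
#' @param verbose print progress messages.
#' @return A `fus_run_result`: `model`, `array`, `source`, `pressure`, `Q`,
#'   `temperature`, `metrics`, optional `reference`/`comparison`, and `log`
#'   (seed, versions, timings, stability bound, applied power factor).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "fus_run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()

  # --- model
  lmap <- if (inherits(config$phantom, "fus_label_map")) config$phantom
          else do.call(phantom_preset,
                       c(config$phantom,
                         list(seed = substream_seed(config$seed, "phantom"))))
  model <- assign_properties(lmap, config$material_table, config$frequency)
  d <- dim(model$speed)
  say("model: %d x %d x %d @ %.3g mm", d[1], d[2], d[3], model$voxel_size)

  # --- source plane at the model front face
  array <- make_array(config$array_spec)
  target <- if (is.null(config$target)) c(0, 0, array$focal_length)
            else config$target
  water <- config$material_table$water
  medium <- list(speed = water$speed_of_sound, density = water$density,
                 attenuation = scale_attenuation(water$attenuation_1MHz,
                                                 config$frequency))
  array <- focus_phases(array, target, medium$speed)
  front_z <- model$origin[3] - model$voxel_size / 2
  if (front_z <= max(array$elements$z))
    stop("configuration error: phantom front face intersects the transducer")
  say("source plane at z = %.1f mm (%d x %d)", front_z, d[1], d[2])
  source <- rayleigh_sommerfeld(array, front_z, d[1:2], model$voxel_size,
                                medium)
  protocols <- config$protocol
  Z_front <- model$density[1, 1, 1] * model$speed[1, 1, 1]
  solve_power <- protocols[[1]]$acoustic_power
  source <- scale_to_power(source, Z_front, solve_power)

  # --- acoustics
  say("HAS propagation (%d reflection passes)", config$settings$reflection_passes)
  pressure <- has_propagate(model, source, config$settings)
  Q <- power_deposition(pressure, model)

  # --- thermal: Q scales linearly with acoustic power, so later protocol
  # entries reuse the single pressure solve
  Qt <- resample_power_deposition(Q, config$thermal_factor)
  thermal <- thermal_model_from_labels(model, config$material_table)
  if (config$thermal_factor > 1L) {
    tm <- resample_thermal_model(thermal, config$thermal_factor)
  } else tm <- thermal
  bound <- stability_bound(tm)
  say("thermal grid %.3g mm, stability bound %.3g s", tm$voxel_size, bound)
  for (p in protocols)
    if (abs(p$acoustic_power - solve_power) > 1e-12 * solve_power)
      stop("protocols with different powers are not supported in one run; ",
           "scale Q manually per segment")
  temperature <- pennes_fdtd(tm, Qt, protocols, dt = config$dt)

  # --- metrics
  pk <- arrayInd(which.max(Mod(pressure$values)), d)[1, ]
  metrics <- list(
    peak_pressure_Pa = max(Mod(pressure$values)),
    peak_voxel = pk,
    fwhm_pressure_mm = tryCatch(fwhm(pressure, model$voxel_size, pk),
                                error = function(e) rep(NA_real_, 3)),
    peak_temperature_rise_C = max(temperature$fields),
    curves = temperature_curves(temperature),
    cotm_mm = tryCatch(center_of_thermal_mass(
      temperature$fields[, , , which.max(apply(temperature$fields, 4, max))],
      temperature$voxel_size, 1.0, temperature$origin),
      error = function(e) rep(NA_real_, 3)))

  result <- list(config = config, model = model, array = array,
                 source = source, pressure = pressure, Q = Q,
                 temperature = temperature, metrics = metrics)

  # --- optional reference solution from the identical source plane
  if (config$reference != "none") {
    say("reference solution: %s", config$reference)
    ref <- switch(config$reference,
      angular_spectrum = expand_plane_to_volume(
        source, model$origin[3] + (seq_len(d[3]) - 1) * model$voxel_size,
        medium$speed, medium$attenuation,
        pad_fraction = config$settings$pad_fraction,
        taper_width = config$settings$edge_taper_width),
      fullwave = fullwave_steady_state(model, source))
    result$reference <- ref
    result$comparison <- comparison_report(pressure, ref, model$voxel_size)
  }

  result$log <- list(
    seed = config$seed, frequency_Hz = config$frequency,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("fusim")),
    stability_bound_s = bound, dt_s = config$dt,
    power_scale_factor = attr(source, "factor"),
    acoustic_power_W = solve_power,
    pad_fraction = config$settings$pad_fraction,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  class(result) <- "fus_run_result"
  result
}

# Thermal model block-averaged to a coarser grid (same scheme as Q).
resample_thermal_model <- function(thermal, factor) {
  blk <- function(x) {
    d <- dim(x); dn <- d %/% factor
    x <- x[seq_len(dn[1] * factor), seq_len(dn[2] * factor),
           seq_len(dn[3] * factor), drop = FALSE]
    a <- array(x, c(factor, dn[1], factor, dn[2], factor, dn[3]))
    apply(a, c(2, 4, 6), mean)
  }
  thermal_model(blk(thermal$conductivity),
                blk(thermal$volumetric_heat_capacity),
                blk(thermal$perfusion),
                thermal$voxel_size * factor,
                thermal$origin + (factor - 1) / 2 * thermal$voxel_size)
}

#' Read / write a run configuration as YAML
#'
#' Serializes every field of a preset-based [run_config()] (phantom spec,
#' array spec, target, protocols, propagation settings, thermal options,
#' reference choice, seed); write-then-read reproduces an identical
#' configuration. Configurations holding an in-memory label map are not
#' serializable here -- store the label map with [write_label_map()] and
#' reference a preset instead.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns a `fus_run_config`;
#'   `write_run_config` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "fus_run_config"))
  if (inherits(config$phantom, "fus_label_map"))
    stop("label-map phantoms are not serializable in a config; ",
         "use write_label_map() and a preset-based config")
  rec <- list(seed = config$seed, frequency = config$frequency,
              phantom = config$phantom, array_spec = config$array_spec,
              target = config$target,
              protocol = lapply(config$protocol, unclass),
              settings = unclass(config$settings),
              thermal_factor = config$thermal_factor, dt = config$dt,
              reference = config$reference)
  yaml::write_yaml(rec, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  r <- yaml::read_yaml(path)
  need <- c("seed", "frequency", "phantom", "protocol", "settings",
            "thermal_factor", "dt", "reference")
  miss <- setdiff(need, names(r))
  if (length(miss))
    stop("config ", path, " lacks mandatory fields: ",
         paste(miss, collapse = ", "))
  run_config(seed = r$seed, frequency = r$frequency, phantom = r$phantom,
             array_spec = if (is.null(r$array_spec)) list() else r$array_spec,
             target = if (is.null(r$target)) NULL else unlist(r$target),
             protocol = lapply(r$protocol, function(p)
               do.call(sonication_protocol, p)),
             settings = do.call(propagation_settings, r$settings),
             thermal_factor = r$thermal_factor, dt = r$dt,
             reference = r$reference)
}

#' Pressure-pattern comparison report
#'
#' The comparison battery applied between a simulated and a reference
#' pressure solution on the same grid: normalized RMS difference over the
#' focal region ([rmsdn_pressure()]), relative peak difference, per-axis
#' FWHM of both patterns, and the earth mover's distance between the
#' transverse focal-plane magnitude patterns (in mm). The EMD is computed on
#' the focal region window (binned to at most 16 bins per side; the exact
#' transport solver is too slow for full dense planes).
#'
#' @param sim,ref [pressure_volume()]s on the same grid (`ref` is the
#'   reference).
#' @param voxel_size mm.
#' @param half_width focal region half-width in voxels.
#' @return Named list of metrics.
#' @export
comparison_report <- function(sim, ref, voxel_size, half_width = 20L) {
  a <- field_magnitude(sim); b <- field_magnitude(ref)
  stopifnot(identical(dim(a), dim(b)))
  d <- dim(a)
  center <- arrayInd(which.max(b), d)[1, ]
  hw <- min(half_width, center - 1L, d - center)
  list(
    rmsdn_percent = rmsdn_pressure(a, b, center, hw),
    region_half_width = hw,
    peak_difference_percent = peak_difference(a, b),
    fwhm_sim_mm = tryCatch(fwhm(a, voxel_size),
                           error = function(e) rep(NA_real_, 3)),
    fwhm_ref_mm = tryCatch(fwhm(b, voxel_size),
                           error = function(e) rep(NA_real_, 3)),
    emd_focal_plane_mm = {
      xr <- (center[1] - hw):(center[1] + hw)
      yr <- (center[2] - hw):(center[2] + hw)
      emd(a[xr, yr, center[3]], b[xr, yr, center[3]], max_side = 16L) *
        voxel_size
    })
}

#' @export
print.fus_run_result <- function(x, ...) {
  cat("<pipeline run>\n")
  cat(sprintf("  seed %d, f = %.4g kHz, %.1f s elapsed\n", x$log$seed,
              x$log$frequency_Hz / 1e3, x$log$elapsed_s))
  cat(sprintf("  peak |p| = %.3g Pa, FWHM = %s mm\n",
              x$metrics$peak_pressure_Pa,
              paste(signif(x$metrics$fwhm_pressure_mm, 3), collapse = " x ")))
  cat(sprintf("  peak temperature rise = %.2f degC\n",
              x$metrics$peak_temperature_rise_C))
  if (!is.null(x$comparison))
    cat(sprintf("  vs reference: RMSDn = %.3g%%, peak diff = %.3g%%\n",
                x$comparison$rmsdn_percent,
                x$comparison$peak_difference_percent))
  invisible(x)
}

#' Serialize a run's metrics and log to JSON
#'
#' Deterministic plain-data report (no field arrays) for archiving a run.
#'
#' @param result a `fus_run_result`.
#' @param path output path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_run_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "fus_run_result"))
  rep <- list(log = result$log, metrics = result$metrics,
              comparison = result$comparison)
  if (is.null(path))
    return(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null"))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
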