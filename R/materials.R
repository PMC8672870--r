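#' Material properties for acoustic and thermal simulation
#'
#' Bundles the measured acoustic and (optionally) thermal properties of one
#' material. Attenuation is the amplitude attenuation coefficient in Np/cm at
#' the 1.0 MHz reference frequency; it is scaled linearly to the operating
#' frequency when a voxel model is assembled (see [scale_attenuation()]).
#' Thermal fields may be `NA` for materials that are only ever used
#' acoustically, but must be present before any thermal simulation touches a
#' voxel of that material.
#'
#' @param name character label.
#' @param speed_of_sound m/s, > 0.
#' @param attenuation_1MHz Np/cm at 1.0 MHz, >= 0.
#' @param density kg/m^3, > 0.
#' @param thermal_conductivity W/m/degC, or `NA`.
#' @param specific_heat J/kg/degC, or `NA`.
#' @return A `fus_material` object (named list).
#' @export
material <- function(name, speed_of_sound, attenuation_1MHz, density,
                     thermal_conductivity = NA_real_, specific_heat = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(speed_of_sound) || speed_of_sound <= 0)
    stop("speed_of_sound must be > 0 for material '", name, "'")
  if (!is.finite(density) || density <= 0)
    stop("density must be > 0 for material '", name, "'")
  if (!is.finite(attenuation_1MHz) || attenuation_1MHz < 0)
    stop("attenuation_1MHz must be >= 0 for material '", name, "'")
  structure(list(
    name = name,
    speed_of_sound = as.numeric(speed_of_sound),
    attenuation_1MHz = as.numeric(attenuation_1MHz),
    density = as.numeric(density),
    thermal_conductivity = as.numeric(thermal_conductivity),
    specific_heat = as.numeric(specific_heat)
  ), class = "fus_material")
}

#' Default material table
#'
#' Measured mean properties of the gelatin phantom materials (porcine
#' ballistics gelatin with 30/50/70% evaporated milk by volume), canola oil,
#' and degassed water. Gelatin and oil acoustic values are through-transmission
#' measurements at 1.0 MHz; oil thermal values are literature values. The 30%
#' and 50% gelatins were only characterized acoustically, so their thermal
#' fields are `NA`. Water thermal properties are standard literature values at
#' room temperature.
#'
#' @return Named list of [material()] objects keyed by material name.
#' @export
default_material_table <- function() {
  mats <- list(
    material("water",       1482.0, 0.000,  998, 0.598, 4182),
    material("gelatin_30",  1552.7, 0.027, 1044),
    material("gelatin_50",  1565.1, 0.034, 1052),
    material("gelatin_70",  1578.5, 0.056, 1093, 0.534, 3316),
    material("canola_oil",  1462.0, 0.008,  940, 0.184, 1913)
  )
  stats::setNames(mats, vapply(mats, `[[`, "", "name"))
}

#' Scale an attenuation coefficient to the operating frequency
#'
#' Attenuation is measured at 1.0 MHz in Np/cm and assumed linear in
#' frequency (exponent fixed at 1); the returned value is in Np/m at the
#' requested frequency.
#'
#' @param alpha_1MHz Np/cm at 1.0 MHz, >= 0.
#' @param frequency Hz, > 0.
#' @return Amplitude attenuation in Np/m at `frequency`.
#' @examples
#' scale_attenuation(0.056, 940e3)  # 5.264 Np/m (70% milk gelatin at 940 kHz)
#' @export
scale_attenuation <- function(alpha_1MHz, frequency) {
  if (any(!is.finite(alpha_1MHz)) || any(alpha_1MHz < 0))
    stop("attenuation must be finite and >= 0")
  if (!is.finite(frequency) || frequency <= 0)
    stop("frequency must be > 0")
  alpha_1MHz * (frequency / 1e6) * 100
}

#' Acoustic impedance of a material
#' @param mat a [material()].
#' @return Z = density * speed of sound, in Rayl.
#' @export
impedance <- function(mat) mat$density * mat$speed_of_sound

#' Read / write a material table as YAML
#'
#' One record per material with the fields of [material()]; `NA` thermal
#' fields are stored as nulls.
#'
#' @param path file path.
#' @param table named list of materials (for writing).
#' @return `read_material_table` returns a named list of materials.
#' @export
read_material_table <- function(path) {
  raw <- yaml::read_yaml(path)
  mats <- lapply(raw, function(r) {
    material(r$name, r$speed_of_sound, r$attenuation_1MHz, r$density,
             if (is.null(r$thermal_conductivity)) NA_real_ else r$thermal_conductivity,
             if (is.null(r$specific_heat)) NA_real_ else r$specific_heat)
  })
  stats::setNames(mats, vapply(mats, `[[`, "", "name"))
}

#' @rdname read_material_table
#' @export
write_material_table <- function(table, path) {
  recs <- lapply(unname(table), function(m) {
    r <- unclass(m)
    r$thermal_conductivity <- if (is.na(r$thermal_conductivity)) NULL else r$thermal_conductivity
    r$specific_heat <- if (is.na(r$specific_heat)) NULL else r$specific_heat
    r
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' @export
print.fus_material <- function(x, ...) {
  cat(sprintf("<material %s>  c = %.1f m/s  alpha = %.3f Np/cm @1MHz  rho = %.0f kg/m^3\n",
              x$name, x$speed_of_sound, x$attenuation_1MHz, x$density))
  if (!is.na(x$thermal_conductivity))
    cat(sprintf("  k = %.3f W/m/degC  c_p = %.0f J/kg/degC\n",
                x$thermal_conductivity, x$specific_heat))
  invisible(x)
}
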