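#' Inclusion specification
#'
#' Describes one oil-balloon inclusion embedded in a host cylinder. A sphere
#' is an ellipsoid with equal semi-axes.
#'
#' Coordinate convention (used repo-wide): right-handed, z is the beam
#' propagation axis, the origin is the transducer face center, all lengths in
#' mm, positions are voxel centers.
#'
#' @param shape `"sphere"` or `"ellipsoid"`.
#' @param center length-3 position (mm).
#' @param semi_axes mm; a scalar radius for a sphere, length-3 for an ellipsoid.
#' @param material material name, must resolve in the material table.
#' @return A `fus_inclusion` object.
#' @export
inclusion <- function(shape = c("sphere", "ellipsoid"), center, semi_axes,
                      material = "canola_oil") {
  shape <- match.arg(shape)
  center <- as.numeric(center)
  stopifnot(length(center) == 3L)
  semi_axes <- as.numeric(semi_axes)
  if (shape == "sphere") {
    stopifnot(length(semi_axes) == 1L)
    semi_axes <- rep(semi_axes, 3L)
  }
  stopifnot(length(semi_axes) == 3L)
  if (any(semi_axes <= 0)) stop("semi_axes must be > 0")
  structure(list(shape = shape, center = center, semi_axes = semi_axes,
                 material = material), class = "fus_inclusion")
}

#' Construct a label map (voxelized segmentation)
#'
#' Low-level constructor; most users build label maps with
#' [build_cylinder_phantom()] or [phantom_preset()].
#'
#' @param labels 3D integer array.
#' @param voxel_size isotropic voxel edge, mm, > 0.
#' @param origin length-3 mm position of the center of voxel (1,1,1).
#' @param label_key named character vector mapping label value (as character)
#'   to material name; every label present in `labels` must appear.
#' @return A `fus_label_map`.
#' @export
label_map <- function(labels, voxel_size, origin, label_key) {
  stopifnot(length(dim(labels)) == 3L, all(dim(labels) >= 1L))
  if (!is.finite(voxel_size) || voxel_size <= 0) stop("voxel_size must be > 0")
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L)
  present <- sort(unique(as.vector(labels)))
  missing <- setdiff(as.character(present), names(label_key))
  if (length(missing))
    stop("labels present in grid but absent from label_key: ",
         paste(missing, collapse = ", "))
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size),
                 origin = origin, label_key = label_key),
            class = "fus_label_map")
}

#' Voxel-center coordinate axes of a gridded object
#' @param x an object with `voxel_size`, `origin` and a 3D grid.
#' @return list of numeric vectors `x`, `y`, `z` (mm, voxel centers).
#' @export
grid_axes <- function(x) {
  d <- dim(if (!is.null(x$labels)) x$labels else x$speed)
  lapply(stats::setNames(1:3, c("x", "y", "z")), function(a)
    x$origin[a] + (seq_len(d[a]) - 1) * x$voxel_size)
}

#' Rasterize a cylindrical phantom with inclusions into a label map
#'
#' The phantom is a cylinder of `diameter` x `height` (axis along z, the beam
#' axis), centered on the axis, with its front (transducer-side) face at
#' `front_z`. Voxels are labeled by a membership test of their center point:
#' the host cylinder overrides the surround (water), and inclusions override
#' the host. Inclusions that extend past the host cylinder are clipped to it
#' with a warning. Deterministic for fixed inputs.
#'
#' @param diameter,height cylinder dimensions, mm.
#' @param host host material name (e.g. `"gelatin_70"`).
#' @param inclusions list of [inclusion()] objects.
#' @param voxel_size isotropic voxel edge, mm.
#' @param surround surround material name, default `"water"`.
#' @param margin transverse water margin around the cylinder, mm.
#' @param front_z z of the phantom front face, mm.
#' @return A [label_map()] with labels 0 = surround, 1 = host, 2... = inclusions
#'   in order of their first appearance in `inclusions`.
#' @export
build_cylinder_phantom <- function(diameter, height, host = "gelatin_70",
                                   inclusions = list(), voxel_size = 0.25,
                                   surround = "water", margin = 2,
                                   front_z = 0) {
  if (!is.finite(voxel_size) || voxel_size <= 0) stop("voxel_size must be > 0")
  if (diameter <= 0 || height <= 0) stop("diameter and height must be > 0")
  h <- voxel_size
  nx <- ny <- ceiling((diameter + 2 * margin) / h)
  nz <- ceiling(height / h)
  origin <- c(-(nx - 1) / 2 * h, -(ny - 1) / 2 * h, front_z + h / 2)
  xs <- origin[1] + (seq_len(nx) - 1) * h
  ys <- origin[2] + (seq_len(ny) - 1) * h
  zs <- origin[3] + (seq_len(nz) - 1) * h

  labels <- array(0L, dim = c(nx, ny, nz))
  r2 <- outer(xs^2, ys^2, `+`)                      # nx x ny
  in_disc <- r2 <= (diameter / 2)^2
  in_z <- zs >= front_z & zs <= front_z + height
  host_mask <- outer(in_disc, in_z, `&`)            # nx x ny x nz
  labels[host_mask] <- 1L

  inc_materials <- character(0)
  for (ii in seq_along(inclusions)) {
    inc <- inclusions[[ii]]
    stopifnot(inherits(inc, "fus_inclusion"))
    lab <- 1L + ii
    inc_materials <- c(inc_materials, inc$material)
    u2 <- outer(((xs - inc$center[1]) / inc$semi_axes[1])^2,
                ((ys - inc$center[2]) / inc$semi_axes[2])^2, `+`)
    w2 <- ((zs - inc$center[3]) / inc$semi_axes[3])^2
    inside <- outer(u2, w2, `+`) <= 1
    if (any(inside & !host_mask)) {
      warning("inclusion ", ii, " (", inc$material,
              ") is clipped by the host cylinder")
      inside <- inside & host_mask
    }
    labels[inside] <- lab
  }

  key <- c(stats::setNames(c(surround, host), c("0", "1")),
           stats::setNames(inc_materials, as.character(seq_along(inc_materials) + 1L)))
  label_map(labels, h, origin, key)
}

#' Assign material properties to a label map
#'
#' Per-voxel lookup of speed of sound, density, and attenuation; attenuation
#' is scaled from the 1 MHz table value to `frequency` with
#' [scale_attenuation()]. Materials without thermal properties are accepted
#' here (the model may be used acoustically only); the thermal solver checks
#' them again. The labels and key are retained on the model for later
#' thermal-property lookup.
#'
#' @param lmap a [label_map()].
#' @param table named list of [material()] objects.
#' @param frequency operating frequency, Hz.
#' @return A `fus_voxel_model` with 3D grids `speed` (m/s), `attenuation`
#'   (Np/m at `frequency`), `density` (kg/m^3).
#' @export
assign_properties <- function(lmap, table = default_material_table(),
                              frequency) {
  stopifnot(inherits(lmap, "fus_label_map"))
  if (!is.finite(frequency) || frequency <= 0) stop("frequency must be > 0")
  present <- sort(unique(as.vector(lmap$labels)))
  mat_names <- lmap$label_key[as.character(present)]
  unknown <- mat_names[!mat_names %in% names(table)]
  if (length(unknown))
    stop("unknown material(s) in label key: ", paste(unknown, collapse = ", "))

  # lookup vectors indexed by position of label in `present`
  idx <- match(lmap$labels, present)
  c_by <- vapply(mat_names, function(m) table[[m]]$speed_of_sound, 0)
  a_by <- vapply(mat_names, function(m)
    scale_attenuation(table[[m]]$attenuation_1MHz, frequency), 0)
  d_by <- vapply(mat_names, function(m) table[[m]]$density, 0)
  dm <- dim(lmap$labels)
  structure(list(
    speed = array(c_by[idx], dm),
    attenuation = array(a_by[idx], dm),
    density = array(d_by[idx], dm),
    voxel_size = lmap$voxel_size,
    origin = lmap$origin,
    frequency = as.numeric(frequency),
    labels = lmap$labels,
    label_key = lmap$label_key
  ), class = "fus_voxel_model")
}

#' Uniform (single-material) voxel model
#'
#' Convenience builder for tests and homogeneous reference runs.
#'
#' @param dim length-3 integer grid dimensions.
#' @param mat a [material()].
#' @param voxel_size mm.
#' @param frequency Hz.
#' @param origin mm position of voxel (1,1,1) center.
#' @return A `fus_voxel_model`.
#' @export
uniform_model <- function(dim, mat, voxel_size, frequency,
                          origin = c(-(dim[1] - 1) / 2 * voxel_size,
                                     -(dim[2] - 1) / 2 * voxel_size,
                                     voxel_size / 2)) {
  lm <- label_map(array(0L, dim), voxel_size, origin,
                  stats::setNames(mat$name, "0"))
  assign_properties(lm, stats::setNames(list(mat), mat$name), frequency)
}

#' Synthetic phantom presets
#'
#' Ready-made label maps mimicking the study's phantom classes:
#' `"p-type-hom"` — homogeneous 102 x 30 mm gelatin cylinder at a chosen milk
#' concentration; `"p-type-het"` — the same cylinder of 70% gelatin with three
#' canola-oil inclusions; `"t-type-het"` — a 102 x 150 mm 70% gelatin cylinder
#' with four oil inclusions in its lower (pre-focal) half. The number, sizes
#' and positions of the oil inclusions in the physical phantoms are not on
#' record, so the presets are plausible illustrative configurations: ellipsoid
#' semi-axes 4-8 mm (4-5 mm in the thin p-type cylinder), placed without
#' overlap, seeded.
#'
#' @param preset one of `"p-type-het"`, `"t-type-het"`, `"p-type-hom"`.
#' @param milk milk concentration (30, 50 or 70) for the homogeneous preset.
#' @param voxel_size mm.
#' @param seed integer controlling randomized inclusion placement.
#' @param front_z z of the phantom front face, mm (standoff from transducer).
#' @return A [label_map()].
#' @export
phantom_preset <- function(preset = c("p-type-het", "t-type-het", "p-type-hom"),
                           milk = 70, voxel_size = 0.25, seed = 1,
                           front_z = 0) {
  preset <- match.arg(preset)
  if (preset == "p-type-hom") {
    host <- paste0("gelatin_", milk)
    if (!milk %in% c(30, 50, 70)) stop("milk must be 30, 50 or 70")
    return(build_cylinder_phantom(102, 30, host, list(), voxel_size,
                                  front_z = front_z))
  }
  dims <- if (preset == "p-type-het") c(102, 30) else c(102, 150)
  n_inc <- if (preset == "p-type-het") 3L else 4L
  # the thin p-type cylinder only accommodates the smaller inclusions
  ax_range <- if (preset == "p-type-het") c(4, 5) else c(4, 8)
  z_margin <- if (preset == "p-type-het") 2 else 10
  z_lo <- front_z + z_margin
  z_hi <- front_z + if (preset == "p-type-het") dims[2] - z_margin
                    else dims[2] / 2
  incs <- place_inclusions(n_inc, dims[1] / 2, z_lo, z_hi, seed, ax_range)
  build_cylinder_phantom(dims[1], dims[2], "gelatin_70", incs, voxel_size,
                         front_z = front_z)
}

# Seeded non-overlapping ellipsoid placement inside a cylinder.
place_inclusions <- function(n, cyl_radius, z_lo, z_hi, seed,
                             ax_range = c(4, 8)) {
  rng <- local_rng(seed)
  incs <- list(); centers <- NULL; radii <- numeric(0)
  tries <- 0L
  while (length(incs) < n && tries < 1000L) {
    tries <- tries + 1L
    ax <- rng$runif(3, ax_range[1], ax_range[2])
    rmax <- max(ax)
    # reject draws that cannot fit in the axial window or the cylinder
    if (z_lo + rmax >= z_hi - rmax || cyl_radius - rmax - 2 <= 0) next
    rr <- sqrt(rng$runif(1)) * (cyl_radius - rmax - 2)
    th <- rng$runif(1, 0, 2 * pi)
    ctr <- c(rr * cos(th), rr * sin(th),
             rng$runif(1, z_lo + rmax, z_hi - rmax))
    ok <- TRUE
    if (length(radii))
      ok <- all(sqrt(colSums((t(centers) - ctr)^2)) > radii + rmax + 1)
    if (ok) {
      incs[[length(incs) + 1L]] <- inclusion("ellipsoid", ctr, ax)
      centers <- rbind(centers, ctr); radii <- c(radii, rmax)
    }
  }
  if (length(incs) < n) stop("could not place ", n, " non-overlapping inclusions")
  incs
}

#' @export
print.fus_label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label map %d x %d x %d @ %.3g mm>\n", d[1], d[2], d[3],
              x$voxel_size))
  tab <- table(x$labels)
  for (l in names(tab))
    cat(sprintf("  %s (%s): %d voxels\n", l, x$label_key[[l]], tab[[l]]))
  invisible(x)
}

#' @export
print.fus_voxel_model <- function(x, ...) {
  d <- dim(x$speed)
  cat(sprintf("<voxel model %d x %d x %d @ %.3g mm, f = %.4g kHz>\n",
              d[1], d[2], d[3], x$voxel_size, x$frequency / 1e3))
  cat(sprintf("  c in [%.1f, %.1f] m/s, alpha in [%.3g, %.3g] Np/m, rho in [%.0f, %.0f] kg/m^3\n",
              min(x$speed), max(x$speed), min(x$attenuation), max(x$attenuation),
              min(x$density), max(x$density)))
  invisible(x)
}
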