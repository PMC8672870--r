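#' Trilinear resampling of a gridded field
#'
#' Resamples a 3D field to a new isotropic voxel size on the same physical
#' extent (the extent is `n * voxel_size` per axis; the target grid covers it
#' with `round(extent / target)` voxels). Interpolation is trilinear with
#' linear extrapolation over the outer half-voxel, so affine fields are
#' reproduced exactly at any spacing.
#'
#' @param field 3D numeric array.
#' @param voxel_size source voxel size, mm.
#' @param target target voxel size, mm, > 0.
#' @return The resampled 3D array, with the target voxel size as attribute
#'   `"voxel_size"` and the offset of the first target voxel center relative
#'   to the first source voxel center as attribute `"offset"` (mm).
#' @export
resample_field <- function(field, voxel_size, target) {
  stopifnot(length(dim(field)) == 3L, target > 0)
  if (abs(target - voxel_size) < 1e-12) {
    attr(field, "voxel_size") <- voxel_size
    attr(field, "offset") <- c(0, 0, 0)
    return(field)
  }
  d <- dim(field)
  m <- pmax(1L, as.integer(round(d * voxel_size / target)))
  # target voxel centers in source index units (source center i at (i-1)*h)
  ax <- lapply(1:3, function(a)
    (-voxel_size / 2 + (seq_len(m[a]) - 0.5) * target) / voxel_size + 1)
  i0 <- lapply(1:3, function(a) pmin(pmax(floor(ax[[a]]), 1), d[a] - 1))
  w <- lapply(1:3, function(a) ax[[a]] - i0[[a]])  # may exceed [0,1] at edges
  out <- array(0, m)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wt <- outer(outer(if (cx) w[[1]] else 1 - w[[1]],
                      if (cy) w[[2]] else 1 - w[[2]]),
                if (cz) w[[3]] else 1 - w[[3]])
    out <- out + wt * field[i0[[1]] + cx, i0[[2]] + cy, i0[[3]] + cz,
                            drop = FALSE]
  }
  attr(out, "voxel_size") <- target
  attr(out, "offset") <- rep((target - voxel_size) / 2, 3)
  out
}

field_magnitude <- function(x) {
  if (inherits(x, "fus_pressure_volume")) Mod(x$values)
  else if (is.complex(x)) Mod(x)
  else x
}

#' Normalized RMS difference between pressure patterns
#'
#' `RMSDn = sqrt( mean( ((|p_sim| - |p_exp|) / p_max_exp)^2 ) ) x 100` over a
#' cubic region of `(2 half_width + 1)^3` voxels centered on `center`. The
#' normalizer is the global maximum of the reference (experimental) pattern
#' over its whole volume, and neither pattern is self-normalized.
#'
#' @param sim,exp [pressure_volume()]s or magnitude arrays on the same grid;
#'   `exp` is the reference.
#' @param center length-3 voxel index of the region center (e.g. the focus).
#' @param half_width region half-width in voxels (default 20, i.e. 41^3).
#' @return Percent.
#' @export
rmsdn_pressure <- function(sim, exp, center, half_width = 20L) {
  s <- field_magnitude(sim); e <- field_magnitude(exp)
  stopifnot(identical(dim(s), dim(e)))
  pmax_exp <- max(e)
  if (pmax_exp == 0) stop("undefined normalizer: reference pattern is zero")
  idx <- lapply(1:3, function(a) (center[a] - half_width):(center[a] + half_width))
  if (any(vapply(1:3, function(a) idx[[a]][1] < 1 || max(idx[[a]]) > dim(s)[a],
                 TRUE)))
    stop("comparison region extends outside the grid")
  r <- (s[idx[[1]], idx[[2]], idx[[3]]] - e[idx[[1]], idx[[2]], idx[[3]]]) / pmax_exp
  sqrt(mean(r^2)) * 100
}

#' RMS difference between temperature frames
#'
#' `RMSD = sqrt(mean((t_sim - t_exp)^2))` in degC over the region, computed on
#' non-normalized temperature rises; the normalized variant divides the
#' residuals by the peak experimental temperature rise (global maximum of the
#' reference frame) and is reported in percent.
#'
#' @param sim,exp 3D temperature-rise arrays on the same grid.
#' @param region optional logical mask or list of index vectors selecting the
#'   comparison region; default is the full grid.
#' @return list with `rmsd` (degC) and `rmsdn` (percent).
#' @export
rmsd_temperature <- function(sim, exp, region = NULL) {
  stopifnot(identical(dim(sim), dim(exp)))
  tmax <- max(exp)
  if (is.null(region)) {
    s <- sim; e <- exp
  } else if (is.logical(region)) {
    s <- sim[region]; e <- exp[region]
  } else {
    s <- sim[region[[1]], region[[2]], region[[3]]]
    e <- exp[region[[1]], region[[2]], region[[3]]]
  }
  if (length(s) == 0) stop("invalid region: empty")
  rmsd <- sqrt(mean((s - e)^2))
  if (tmax <= 0) stop("undefined normalizer: reference has no temperature rise")
  list(rmsd = rmsd, rmsdn = sqrt(mean(((s - e) / tmax)^2)) * 100)
}

#' Full width at half maximum along the grid axes
#'
#' For each axis, takes the 1D profile through the global peak voxel, walks
#' outward from the peak to the first crossings below half maximum, locates
#' them by linear interpolation, and returns the distance between the
#' outermost crossings of the main lobe. Scale-invariant. A profile that
#' never falls below half maximum within the grid is an error
#' (unbounded lobe).
#'
#' @param field 3D magnitude array.
#' @param voxel_size mm.
#' @param peak optional length-3 voxel index of the peak; default the global
#'   maximum (ties broken by lowest linear index).
#' @return Length-3 numeric, mm per axis.
#' @export
fwhm <- function(field, voxel_size, peak = NULL) {
  field <- field_magnitude(field)
  d <- dim(field)
  if (is.null(peak)) peak <- arrayInd(which.max(field), d)[1, ]
  half <- field[peak[1], peak[2], peak[3]] / 2
  vapply(1:3, function(a) {
    prof <- switch(a,
                   field[, peak[2], peak[3]],
                   field[peak[1], , peak[3]],
                   field[peak[1], peak[2], ])
    i <- peak[a]
    cross <- function(dir) {
      j <- i
      while (j + dir >= 1 && j + dir <= d[a] && prof[j + dir] >= half)
        j <- j + dir
      if (j + dir < 1 || j + dir > d[a])
        stop("unbounded lobe: profile never falls below half maximum (axis ",
             a, ")")
      # linear interpolation between prof[j] (>= half) and prof[j+dir] (< half)
      j + dir * (prof[j] - half) / (prof[j] - prof[j + dir])
    }
    (cross(1L) - cross(-1L)) * voxel_size
  }, 0)
}

#' Relative peak difference between two magnitude patterns
#'
#' `|max|sim| - max|exp|| / max|exp| x 100`; asymmetric in its arguments
#' (the second is the reference).
#'
#' @param sim,exp magnitude arrays or [pressure_volume()]s.
#' @return Percent.
#' @export
peak_difference <- function(sim, exp) {
  ps <- max(field_magnitude(sim)); pe <- max(field_magnitude(exp))
  if (pe == 0) stop("undefined: reference peak is zero")
  abs(ps - pe) / pe * 100
}

#' Center of thermal mass
#'
#' Temperature-rise-weighted centroid of the voxels with `dT >= threshold`.
#'
#' @param frame 3D temperature-rise array, degC.
#' @param voxel_size mm.
#' @param threshold degC (default 1.0).
#' @param origin mm position of voxel (1,1,1) center.
#' @return Length-3 mm point.
#' @export
center_of_thermal_mass <- function(frame, voxel_size, threshold = 1.0,
                                   origin = c(0, 0, 0)) {
  sel <- which(frame >= threshold)
  if (length(sel) == 0) stop("empty mass: no voxel at or above threshold")
  idx <- arrayInd(sel, dim(frame))
  wts <- frame[sel]
  origin + (colSums(idx * wts) / sum(wts) - 1) * voxel_size
}

#' Distance between two centers of thermal mass
#' @param a,b length-3 mm points (see [center_of_thermal_mass()]).
#' @return mm.
#' @export
delta_cotm <- function(a, b) sqrt(sum((a - b)^2))

#' Peak and mean temperature curves
#'
#' The peak curve is the maximum temperature rise per frame over the whole
#' volume. The mean curve averages, per frame, the cubic voxel neighborhood
#' (nearest odd cube to `cube_volume`; 5 x 5 x 5 at 0.5 mm for the 16 mm^3
#' default) centered on the spatiotemporal peak voxel (ties broken by lowest
#' linear index). A cube clipped by the domain boundary is averaged over the
#' intersection with a warning.
#'
#' @param series a [temperature_series()].
#' @param cube_volume mm^3 for the mean region.
#' @return list with `times`, `peak`, `mean`, `peak_voxel`, `cube_side`.
#' @export
temperature_curves <- function(series, cube_volume = 16) {
  stopifnot(inherits(series, "fus_temperature_series"))
  f <- series$fields
  d <- dim(f)
  nt <- d[4]
  peak_curve <- vapply(seq_len(nt), function(i) max(f[, , , i]), 0)
  side_vox <- max(1L, as.integer(2 * floor(cube_volume^(1 / 3) /
                                           series$voxel_size / 2) + 1))
  pk <- arrayInd(which.max(f), d)[1, ]
  hw <- (side_vox - 1L) %/% 2L
  rng <- lapply(1:3, function(a)
    max(1L, pk[a] - hw):min(d[a], pk[a] + hw))
  if (any(vapply(rng, length, 1L) < side_vox))
    warning("mean region clipped by the domain boundary")
  mean_curve <- vapply(seq_len(nt), function(i)
    mean(f[rng[[1]], rng[[2]], rng[[3]], i]), 0)
  list(times = series$times, peak = peak_curve, mean = mean_curve,
       peak_voxel = pk[1:3], cube_side = side_vox)
}
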