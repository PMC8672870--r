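#' Complex pressure plane
#'
#' A 2D transverse map of the steady-state complex pressure phasor (Pa, peak
#' amplitude convention: `|p|` is the peak pressure). Phasor time convention
#' is `e^{+j w t}` with forward propagation `e^{-j k z}`, used repo-wide.
#' The plane is centered on the beam (z) axis unless `origin_xy` says
#' otherwise.
#'
#' @param values complex matrix (nx x ny).
#' @param pixel_size mm, > 0.
#' @param plane_z axial position of the plane, mm.
#' @param frequency Hz.
#' @param origin_xy mm position of pixel (1,1) center; default centers the
#'   plane on the axis.
#' @return A `fus_pressure_plane`.
#' @export
pressure_plane <- function(values, pixel_size, plane_z, frequency,
                           origin_xy = NULL) {
  values <- as_complex_matrix(values)
  if (!is.finite(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  if (!all(is.finite(Re(values)) & is.finite(Im(values))))
    stop("invalid field: non-finite values")
  d <- dim(values)
  if (is.null(origin_xy))
    origin_xy <- -(d - 1) / 2 * pixel_size
  structure(list(values = values, pixel_size = as.numeric(pixel_size),
                 plane_z = as.numeric(plane_z), frequency = as.numeric(frequency),
                 origin_xy = as.numeric(origin_xy)),
            class = "fus_pressure_plane")
}

#' Complex pressure volume
#'
#' @param values complex 3D array (Pa phasor).
#' @param voxel_size mm.
#' @param origin mm position of voxel (1,1,1) center.
#' @param frequency Hz.
#' @return A `fus_pressure_volume`.
#' @export
pressure_volume <- function(values, voxel_size, origin, frequency) {
  stopifnot(length(dim(values)) == 3L)
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), frequency = as.numeric(frequency)),
            class = "fus_pressure_volume")
}

as_complex_matrix <- function(v) {
  stopifnot(length(dim(v)) == 2L)
  if (!is.complex(v)) storage.mode(v) <- "complex"
  v
}

# FFT sample frequencies (cycles per unit), numpy fftfreq layout.
fft_freq <- function(n, d) {
  c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1)) / (n * d)
}

# Smallest 5-smooth integer >= n (keeps R's mixed-radix FFT fast).
next_fast_size <- function(n) {
  while (TRUE) {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# Raised-cosine edge window over `width` pixels at each border of an n-vector.
cosine_edge <- function(n, width) {
  w <- rep(1, n)
  if (width > 0) {
    width <- min(width, floor(n / 2))
    t <- (seq_len(width) - 0.5) / width
    ramp <- 0.5 * (1 - cos(pi * t))
    w[seq_len(width)] <- ramp
    w[n + 1 - seq_len(width)] <- ramp
  }
  w
}

# Zero-pad a matrix to (np x np2) with the original centered; returns the
# padded matrix and the index ranges of the original region.
pad_matrix <- function(m, npad) {
  d <- dim(m)
  out <- matrix(0 + 0i, npad[1], npad[2])
  i0 <- floor((npad - d) / 2)
  ix <- i0[1] + seq_len(d[1]); iy <- i0[2] + seq_len(d[2])
  out[ix, iy] <- m
  list(field = out, ix = ix, iy = iy)
}

# Axial wavenumber grid and spectral propagation factor for one step.
# k may be complex (attenuation as negative imaginary part). Returns the
# factor e^{-j kz d} with the branch Im(kz) <= 0 so evanescent components
# decay; `evanescent` = "zero" nulls them instead (useful for unitarity).
spectral_factor <- function(kt2, k, dist_m, evanescent = c("decay", "zero")) {
  evanescent <- match.arg(evanescent)
  kz <- sqrt(as.complex(k^2 - kt2))
  flip <- Im(kz) > 0
  kz[flip] <- -kz[flip]
  evan <- kt2 > Re(k)^2
  d_eff <- rep(dist_m, length(kz))
  d_eff[evan] <- abs(dist_m)   # evanescent components decay for either direction
  fac <- exp(-1i * kz * d_eff)
  if (evanescent == "zero") fac[evan] <- 0
  dim(fac) <- dim(kt2)
  fac
}

# Squared transverse wavenumber grid (rad/m)^2 for an (nx x ny) plane.
kt2_grid <- function(nx, ny, pixel_m) {
  kx <- 2 * pi * fft_freq(nx, pixel_m)
  ky <- 2 * pi * fft_freq(ny, pixel_m)
  outer(kx^2, ky^2, `+`)
}

#' Homogeneous angular-spectrum propagation of a pressure plane
#'
#' Propagates a monochromatic complex pressure plane by `distance` through a
#' uniform medium: FFT, multiplication by `e^{-j kz d}` with
#' `kz = sqrt(k^2 - kx^2 - ky^2)` and complex wavenumber
#' `k = 2 pi f / c - j alpha`, inverse FFT. Negative distances back-propagate.
#' Evanescent components (`kx^2 + ky^2 > Re(k)^2`) either decay (default) or
#' are zeroed.
#'
#' @param plane a [pressure_plane()].
#' @param distance mm (may be negative).
#' @param speed m/s.
#' @param attenuation Np/m at the plane's frequency.
#' @param evanescent `"decay"` or `"zero"`.
#' @param pad_fraction zero-padding per side as a fraction of the grid size.
#' @param taper_width raised-cosine roll-off width (pixels) applied to the
#'   field edges before the FFT; 0 disables (exact for periodic fields such
#'   as normally incident plane waves).
#' @return The propagated [pressure_plane()] at `plane_z + distance`.
#' @export
angular_spectrum_step <- function(plane, distance, speed, attenuation = 0,
                                  evanescent = c("decay", "zero"),
                                  pad_fraction = 0, taper_width = 0) {
  evanescent <- match.arg(evanescent)
  stopifnot(inherits(plane, "fus_pressure_plane"))
  v <- plane$values
  if (!all(is.finite(Re(v)) & is.finite(Im(v)))) stop("invalid field: non-finite values")
  if (speed <= 0) stop("speed must be > 0")
  d <- dim(v)
  if (taper_width > 0)
    v <- v * outer(cosine_edge(d[1], taper_width), cosine_edge(d[2], taper_width))
  npad <- vapply(d, function(n) next_fast_size(as.integer(ceiling(n * (1 + 2 * pad_fraction)))), 1L)
  p <- pad_matrix(v, npad)
  kt2 <- kt2_grid(npad[1], npad[2], plane$pixel_size * 1e-3)
  k <- 2 * pi * plane$frequency / speed - 1i * attenuation
  fac <- spectral_factor(kt2, k, distance * 1e-3, evanescent)
  out <- stats::fft(stats::fft(p$field) * fac, inverse = TRUE) / prod(npad)
  pressure_plane(out[p$ix, p$iy], plane$pixel_size, plane$plane_z + distance,
                 plane$frequency, plane$origin_xy)
}

#' Expand a pressure plane into a volume through a homogeneous medium
#'
#' Direct angular-spectrum steps from the source plane to each requested z
#' (no accumulation of stepping error).
#'
#' @inheritParams angular_spectrum_step
#' @param z_targets axial positions, mm (equally spaced for a regular volume).
#' @return A [pressure_volume()] whose slab i is the field at `z_targets[i]`.
#' @export
expand_plane_to_volume <- function(plane, z_targets, speed, attenuation = 0,
                                   evanescent = c("decay", "zero"),
                                   pad_fraction = 0, taper_width = 0) {
  evanescent <- match.arg(evanescent)
  stopifnot(length(z_targets) >= 1L)
  d <- dim(plane$values)
  v <- plane$values
  if (taper_width > 0)
    v <- v * outer(cosine_edge(d[1], taper_width), cosine_edge(d[2], taper_width))
  npad <- vapply(d, function(n) next_fast_size(as.integer(ceiling(n * (1 + 2 * pad_fraction)))), 1L)
  p <- pad_matrix(v, npad)
  F0 <- stats::fft(p$field)
  kt2 <- kt2_grid(npad[1], npad[2], plane$pixel_size * 1e-3)
  k <- 2 * pi * plane$frequency / speed - 1i * attenuation
  out <- array(0 + 0i, c(d, length(z_targets)))
  for (j in seq_along(z_targets)) {
    fac <- spectral_factor(kt2, k, (z_targets[j] - plane$plane_z) * 1e-3, evanescent)
    pl <- stats::fft(F0 * fac, inverse = TRUE) / prod(npad)
    out[, , j] <- pl[p$ix, p$iy]
  }
  dz <- if (length(z_targets) > 1) diff(z_targets)[1] else plane$pixel_size
  pressure_volume(out, plane$pixel_size,
                  c(plane$origin_xy, z_targets[1]), plane$frequency)
}

#' @export
print.fus_pressure_plane <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pressure plane %d x %d @ %.3g mm, z = %.2f mm, f = %.4g kHz, max |p| = %.4g Pa>\n",
              d[1], d[2], x$pixel_size, x$plane_z, x$frequency / 1e3,
              max(Mod(x$values))))
  invisible(x)
}

#' @export
print.fus_pressure_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pressure volume %d x %d x %d @ %.3g mm, f = %.4g kHz, max |p| = %.4g Pa>\n",
              d[1], d[2], d[3], x$voxel_size, x$frequency / 1e3, max(Mod(x$values))))
  invisible(x)
}
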