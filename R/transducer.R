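#' Build a phased-array transducer
#'
#' Lays out circular elements of equal area on the rectangular portion of a
#' spherical shell whose center of curvature is the geometric focus at
#' `(0, 0, focal_length)`; the shell apex (transducer face center) is the
#' coordinate origin. The default preset mirrors the study transducer:
#' 256 elements, 940 kHz, 10 cm focal length, 14.4 x 9.8 cm aperture. The
#' physical element layout of that array is not on record, so the default
#' layout is deterministic seeded pseudo-random sequential placement of
#' non-overlapping equal circles; consequently absolute focal dimensions are
#' close to, but not replicas of, the physical array's.
#'
#' @param spec list with fields `frequency_Hz`, `focal_length_mm`,
#'   `aperture_mm` (length 2), `n_elements`, `element_radius_mm`,
#'   `layout_seed`; missing fields take the preset defaults.
#' @return A `fus_array` with `elements` (data.frame: x, y, z mm on the
#'   shell; area mm^2; complex `drive`), `frequency`, `focal_length`,
#'   `aperture`.
#' @export
make_array <- function(spec = list()) {
  def <- list(frequency_Hz = 940e3, focal_length_mm = 100,
              aperture_mm = c(144, 98), n_elements = 256L,
              element_radius_mm = 2.5, layout_seed = 1L)
  spec <- utils::modifyList(def, spec)
  Fmm <- spec$focal_length_mm
  ap <- spec$aperture_mm
  r <- spec$element_radius_mm
  n <- spec$n_elements
  if (any(ap / 2 >= Fmm)) stop("configuration error: aperture exceeds shell extent")
  if (n * pi * r^2 > 0.55 * prod(ap))
    stop("configuration error: infeasible packing (element area exceeds ~55% of aperture)")

  if (n == 1L) {
    xy <- matrix(0, 1, 2)
  } else {
    rng <- local_rng(spec$layout_seed)
    xy <- matrix(NA_real_, n, 2)
    placed <- 0L; tries <- 0L
    lim <- ap / 2 - r
    while (placed < n) {
      tries <- tries + 1L
      if (tries > 200000L)
        stop("configuration error: infeasible packing (could not place ",
             n, " elements)")
      cand <- c(rng$runif(1, -lim[1], lim[1]), rng$runif(1, -lim[2], lim[2]))
      if (placed == 0L ||
          all((xy[seq_len(placed), 1] - cand[1])^2 +
              (xy[seq_len(placed), 2] - cand[2])^2 > (2 * r + 0.2)^2)) {
        placed <- placed + 1L
        xy[placed, ] <- cand
      }
    }
  }
  z <- Fmm - sqrt(Fmm^2 - xy[, 1]^2 - xy[, 2]^2)
  elements <- data.frame(x = xy[, 1], y = xy[, 2], z = z,
                         area = rep(pi * r^2, n))
  elements$drive <- rep(complex(real = 1, imaginary = 0), n)
  structure(list(elements = elements, frequency = spec$frequency_Hz,
                 focal_length = Fmm, aperture = ap,
                 element_radius = r),
            class = "fus_array")
}

#' Set element phases to focus at a target point
#'
#' Each element's drive phase is set so that all contributions arrive in
#' phase at `target`: with the repo convention (`e^{+j w t}`, forward factor
#' `e^{-j k r}`), the phase is `+k (d_i - focal_length)` where `d_i` is the
#' element-target distance. At the geometric focus all phases are zero.
#'
#' @param array a `fus_array`.
#' @param target length-3 mm point.
#' @param speed m/s of the coupling medium.
#' @return The array with updated complex drives (amplitudes unchanged).
#' @export
focus_phases <- function(array, target, speed) {
  stopifnot(inherits(array, "fus_array"), speed > 0)
  el <- array$elements
  d <- sqrt((el$x - target[1])^2 + (el$y - target[2])^2 + (el$z - target[3])^2)
  k <- 2 * pi * array$frequency / speed / 1e3  # rad/mm
  array$elements$drive <- Mod(el$drive) * exp(1i * k * (d - array$focal_length))
  array
}

# Sub-sources on the shell for one element: sunflower points on the tangent
# disc, projected back onto the sphere about the focus. Returns positions (m)
# and per-point area (m^2).
element_subsources <- function(cx, cy, cz, radius_mm, area_mm2, Fmm, lambda_mm,
                               max_spacing = lambda_mm / 4) {
  nsub <- max(1L, as.integer(ceiling(pi * radius_mm^2 / max_spacing^2)))
  focus <- c(0, 0, Fmm)
  nrm <- (focus - c(cx, cy, cz)) / Fmm
  ref <- if (abs(nrm[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- pracma_cross(nrm, ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma_cross(nrm, e1)
  if (nsub == 1L) {
    pts <- matrix(c(cx, cy, cz), 1, 3)
  } else {
    i <- seq_len(nsub)
    rr <- radius_mm * sqrt((i - 0.5) / nsub)
    th <- i * pi * (3 - sqrt(5))
    pts <- cbind(cx + rr * cos(th) * e1[1] + rr * sin(th) * e2[1],
                 cy + rr * cos(th) * e1[2] + rr * sin(th) * e2[2],
                 cz + rr * cos(th) * e1[3] + rr * sin(th) * e2[3])
    v <- sweep(pts, 2, focus)           # project onto the shell
    vn <- sqrt(rowSums(v^2))
    pts <- sweep(v * (Fmm / vn), 2, focus, `+`)
  }
  list(pos_m = pts * 1e-3, dA_m2 = rep(area_mm2 * 1e-6 / nsub, nrow(pts)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# All sub-sources of an array with their complex strengths
# (j w rho u dA / 2 pi per sub-source).
array_subsources <- function(array, medium, max_spacing_mm = NULL) {
  lambda_mm <- medium$speed / array$frequency * 1e3
  if (is.null(max_spacing_mm)) max_spacing_mm <- lambda_mm / 4
  el <- array$elements
  parts <- lapply(seq_len(nrow(el)), function(i)
    element_subsources(el$x[i], el$y[i], el$z[i], array$element_radius,
                       el$area[i], array$focal_length, lambda_mm,
                       max_spacing_mm))
  pos <- do.call(rbind, lapply(parts, `[[`, "pos_m"))
  dA <- unlist(lapply(parts, `[[`, "dA_m2"))
  drive <- rep(el$drive, vapply(parts, function(p) length(p$dA_m2), 1L))
  omega <- 2 * pi * array$frequency
  list(pos = pos, amp = 1i * omega * medium$density * drive * dA / (2 * pi))
}

#' Rayleigh-Sommerfeld field of an array at arbitrary points
#'
#' Direct summation `p(r) = sum_i (j w rho u dA / 2 pi) e^{-jkr - a r} / r`
#' over element sub-sources, with each element subdivided until the sub-source
#' spacing is at most `lambda/4` (halving the spacing changes the focal value
#' by well under 0.5%). Elements drive with uniform normal velocity equal to
#' the modulus of their complex drive (m/s).
#'
#' @param array a `fus_array`.
#' @param points n x 3 matrix of observation points, mm.
#' @param medium list with `speed` (m/s), `density` (kg/m^3), `attenuation`
#'   (Np/m); homogeneous (water by default).
#' @param max_spacing_mm optional sub-source spacing override (mm).
#' @return Complex pressure vector (Pa phasor). Observation points coincident
#'   with a sub-source are skipped with a warning.
#' @export
rs_field_points <- function(array, points, medium = water_medium(),
                            max_spacing_mm = NULL) {
  stopifnot(inherits(array, "fus_array"))
  points <- matrix(as.numeric(points), ncol = 3)
  ss <- array_subsources(array, medium, max_spacing_mm)
  k <- 2 * pi * array$frequency / medium$speed
  p <- .rs_sum(ss$pos, ss$amp, points * 1e-3, k, medium$attenuation, 1e-9)
  if (attr(p, "skipped") > 0)
    warning(attr(p, "skipped"),
            " observation/sub-source coincidences excluded from the sum")
  attr(p, "skipped") <- NULL
  p
}

#' Rayleigh-Sommerfeld source plane
#'
#' Evaluates the array field on a transverse plane (the model front face),
#' the one-time Rayleigh-Sommerfeld step that seeds the angular-spectrum
#' propagation.
#'
#' @param array a `fus_array`.
#' @param plane_z axial position of the plane, mm.
#' @param n length-2 grid size (nx, ny).
#' @param pixel_size mm.
#' @param medium homogeneous medium (water by default).
#' @param max_spacing_mm optional sub-source spacing override (mm).
#' @return A [pressure_plane()].
#' @export
rayleigh_sommerfeld <- function(array, plane_z, n, pixel_size,
                                medium = water_medium(),
                                max_spacing_mm = NULL) {
  n <- rep(as.integer(n), length.out = 2)
  ox <- -(n - 1) / 2 * pixel_size
  xs <- ox[1] + (seq_len(n[1]) - 1) * pixel_size
  ys <- ox[2] + (seq_len(n[2]) - 1) * pixel_size
  pts <- cbind(rep(xs, times = n[2]), rep(ys, each = n[1]), plane_z)
  p <- rs_field_points(array, pts, medium, max_spacing_mm)
  pressure_plane(matrix(p, n[1], n[2]), pixel_size, plane_z, array$frequency)
}

#' Degassed-water coupling medium defaults
#' @param attenuation Np/m (0 for degassed water).
#' @return list with `speed`, `density`, `attenuation`.
#' @export
water_medium <- function(attenuation = 0) {
  list(speed = 1482, density = 998, attenuation = attenuation)
}

#' Scale a source plane to a target acoustic power
#'
#' Multiplies the field by the single real factor that makes the
#' plane-integrated intensity `sum(|p|^2 / 2Z) * pixel_area` equal
#' `target_power` (plane-wave approximation). Refuses if the beam is clipped
#' at the plane edge: more than 1% of the plane-integrated energy on the
#' one-pixel border ring. An energy criterion is used rather than a border
#' amplitude one because sparse random arrays carry an incoherent sidelobe
#' floor near `1/sqrt(n_elements)` in amplitude (which says nothing about
#' lost power), while a truly clipped main lobe always places percents of the
#' total energy on the ring.
#'
#' @param plane a [pressure_plane()].
#' @param impedance Rayl of the medium at the plane.
#' @param target_power W, > 0.
#' @return The scaled plane, with the applied factor as attribute `"factor"`.
#' @export
scale_to_power <- function(plane, impedance, target_power) {
  stopifnot(inherits(plane, "fus_pressure_plane"), target_power > 0)
  e <- Mod(plane$values)^2
  ring <- c(e[1, ], e[nrow(e), ], e[, 1], e[, ncol(e)]) # corners counted twice: negligible
  frac <- sum(ring) / sum(e)
  if (frac >= 0.01)
    stop("beam clipped at plane edge (", signif(frac * 100, 3),
         "% of the plane energy on the border ring); enlarge the plane")
  current <- plane_power(plane, impedance)
  fac <- sqrt(target_power / current)
  out <- pressure_plane(plane$values * fac, plane$pixel_size, plane$plane_z,
                        plane$frequency, plane$origin_xy)
  attr(out, "factor") <- fac
  out
}

#' Plane-integrated acoustic power
#' @param plane a [pressure_plane()].
#' @param impedance Rayl.
#' @return W.
#' @export
plane_power <- function(plane, impedance) {
  sum(Mod(plane$values)^2 / (2 * impedance)) * (plane$pixel_size * 1e-3)^2
}

#' @export
print.fus_array <- function(x, ...) {
  cat(sprintf("<phased array: %d elements, f = %.4g kHz, F = %.0f mm, aperture %.0f x %.0f mm>\n",
              nrow(x$elements), x$frequency / 1e3, x$focal_length,
              x$aperture[1], x$aperture[2]))
  invisible(x)
}
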