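#' Full-wave steady-state Helmholtz solution on a heterogeneous voxel model
#'
#' Independent reference solver for cross-validating the split-step HAS
#' propagator: solves the heterogeneous Helmholtz equation
#' `laplacian(u) + k(r)^2 u = -s` (complex wavenumber
#' `k = 2 pi f / c - j alpha`, time convention `e^{+j w t}`) to steady state
#' with a convergent Born series -- a preconditioned Richardson iteration
#' whose Green's operator is applied by 3D FFT (pseudospectral). Unlike the
#' one-way split-step scheme it makes no paraxial or forward-only
#' approximation: diffraction, refraction, scattering and multiple
#' reflections from sound-speed and absorption heterogeneity are all
#' captured. (Density heterogeneity is not part of this operator; as in the
#' HAS forward pass, density enters the pipeline through impedance in
#' reflection coefficients and power deposition.)
#'
#' The source plane is injected as an equivalent source sheet whose spectrum
#' is `2 j k_z P(kx, ky) / dz`, which radiates the prescribed complex pressure
#' forward from the model front face (a mirror copy radiates backward into
#' the front absorbing layer). The domain is padded with absorbing layers in
#' which the imaginary part of `k^2` ramps quadratically; the series
#' contraction parameter `eps` is set to 1.05 x the maximum modulus of
#' `k^2 - k0^2` over the padded domain, which guarantees convergence.
#'
#' @param model a `fus_voxel_model`.
#' @param source a [pressure_plane()] registered to the model front face
#'   (same grid/pixel conventions as [has_propagate()]).
#' @param pad_xy,pad_z absorbing-layer thickness in voxels (per side).
#' @param boundary_max peak added `|Im(k^2)|` in the absorbing layers; the
#'   default targets a one-way amplitude suppression of about `e^{-1.5}`
#'   through the axial layer.
#' @param tol relative update norm at which the series is declared converged.
#' @param max_iter iteration cap (warns if reached).
#' @param verbose print residuals every 10 iterations.
#' @return A [pressure_volume()] on the model grid; attributes `iterations`
#'   and `residual` record the convergence state.
#' @export
fullwave_steady_state <- function(model, source, pad_xy = 16L, pad_z = 32L,
                                  boundary_max = NULL, tol = 2e-4,
                                  max_iter = 300L, verbose = FALSE) {
  stopifnot(inherits(model, "fus_voxel_model"),
            inherits(source, "fus_pressure_plane"))
  if (abs(model$frequency - source$frequency) > 1e-6 * model$frequency)
    stop("configuration error: source/model frequency mismatch")
  d <- dim(model$speed)
  if (!all(dim(source$values) == d[1:2]))
    stop("configuration error: source plane grid does not match model")
  h <- model$voxel_size * 1e-3
  omega <- 2 * pi * model$frequency

  k2 <- (omega / model$speed - 1i * model$attenuation)^2
  k0_sq <- (min(Re(k2)) + max(Re(k2))) / 2
  k0 <- sqrt(k0_sq)

  # padded grid: edge-replicated medium plus quadratic absorption ramps
  np <- c(next_fast_size(d[1] + 2L * pad_xy),
          next_fast_size(d[2] + 2L * pad_xy),
          next_fast_size(d[3] + 2L * pad_z + 1L))  # +1 plane for the source sheet
  i0 <- floor((np[1:2] - d[1:2]) / 2)
  ix <- i0[1] + seq_len(d[1]); iy <- i0[2] + seq_len(d[2])
  z_src <- pad_z + 1L                      # source sheet plane
  iz <- z_src + seq_len(d[3])              # model planes; the sheet spectrum is
  # back-shifted by dz/2 below so plane iz[i] samples the voxel *center*
  # z = origin[3] + (i - 1) * voxel_size, matching the HAS registration

  rep_idx <- function(n, i) pmin(pmax(seq_len(n) - (i[1] - 1L), 1L), length(i))
  k2p <- k2[rep_idx(np[1], ix), , , drop = FALSE]
  k2p <- k2p[, rep_idx(np[2], iy), , drop = FALSE]
  k2p <- k2p[, , rep_idx(np[3], iz), drop = FALSE]

  if (is.null(boundary_max)) boundary_max <- 9 * k0 / (pad_z * h)
  ramp <- function(n, idx) { # 0 inside, ->1 at outer edges
    lo <- idx[1]; hi <- idx[length(idx)]
    r <- rep(0, n)
    if (lo > 1) r[1:(lo - 1)] <- ((lo - 1):1 / (lo - 1))^2
    if (hi < n) r[(hi + 1):n] <- (1:(n - hi) / (n - hi))^2
    r
  }
  bnd <- pmax(pmax(outer(ramp(np[1], ix), rep(1, np[2])),
                   outer(rep(1, np[1]), ramp(np[2], iy))))
  bnd <- outer(bnd, rep(1, np[3]))
  rz <- ramp(np[3], (z_src):(iz[length(iz)]))
  bnd <- pmax(bnd, outer(matrix(1, np[1], np[2]), rz))
  k2p <- k2p - 1i * boundary_max * bnd
  rm(bnd)

  eps <- 1.05 * max(Mod(k2p - k0_sq))
  V <- k2p - k0_sq + 1i * eps
  rm(k2p)
  gam <- (-1i / eps) * V

  kx <- 2 * pi * fft_freq(np[1], h); ky <- 2 * pi * fft_freq(np[2], h)
  kz <- 2 * pi * fft_freq(np[3], h)
  p2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  Ghat <- 1 / (p2 - k0_sq + 1i * eps)
  rm(p2)

  # source sheet: spectrum 2 j k_z P / dz on the plane z = z_src
  sp <- matrix(0 + 0i, np[1], np[2])
  sp[ix, iy] <- source$values
  k_src <- omega / model$speed[1, 1, 1]   # front-face medium
  kt2 <- kt2_grid(np[1], np[2], h)
  kzs <- sqrt(as.complex(k_src^2 - kt2))
  kzs[kt2 > (0.95 * k_src)^2] <- 0        # drop near-evanescent content
  # e^{+j kz dz/2}: registers the prescribed plane half a voxel before the
  # first sampled model plane, so sampled planes sit at voxel centers
  s_plane <- stats::fft(2i * kzs * exp(1i * kzs * h / 2) * stats::fft(sp),
                        inverse = TRUE) / prod(np[1:2]) / h

  u <- array(0 + 0i, np)
  nvox <- prod(np)
  res <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    w <- V * u
    w[, , z_src] <- w[, , z_src] + s_plane
    w <- stats::fft(stats::fft(w) * Ghat, inverse = TRUE) / nvox
    du <- gam * (w - u)
    u <- u + du
    if (it %% 5L == 0L || it == max_iter) {
      res <- sqrt(sum(Mod(du)^2) / max(sum(Mod(u)^2), .Machine$double.xmin))
      if (verbose) message(sprintf("  born iter %d: rel update %.3g", it, res))
      if (res < tol) break
    }
  }
  if (res >= tol)
    warning(sprintf("Born series not converged to %g after %d iterations (residual %.3g)",
                    tol, it, res))
  out <- pressure_volume(u[ix, iy, iz], model$voxel_size, model$origin,
                         model$frequency)
  attr(out, "iterations") <- it
  attr(out, "residual") <- res
  attr(out, "eps") <- eps
  out
}
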