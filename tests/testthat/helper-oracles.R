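# Independent oracles used across the test suite.

# Earth mover's distance via an exact linear program (boot::simplex), fully
# independent of the package's transportation simplex. One redundant demand
# constraint is dropped (the balanced problem makes it implied).
lp_emd <- function(pattern_a, pattern_b) {
  pa <- pattern_a / sum(pattern_a)
  pb <- pattern_b / sum(pattern_b)
  ia <- which(pa > 0, arr.ind = TRUE); wa <- pa[pa > 0]
  ib <- which(pb > 0, arr.ind = TRUE); wb <- pb[pb > 0]
  m <- length(wa); n <- length(wb)
  cost <- sqrt(outer(ia[, 1], ib[, 1], `-`)^2 + outer(ia[, 2], ib[, 2], `-`)^2)
  A3 <- matrix(0, m + n - 1, m * n)
  for (i in seq_len(m)) A3[i, i + m * (0:(n - 1))] <- 1
  if (n > 1) for (j in seq_len(n - 1)) A3[m + j, (j - 1) * m + seq_len(m)] <- 1
  unname(boot::simplex(a = as.vector(cost), A3 = A3, b3 = c(wa, wb[-n]),
                       maxi = FALSE)$value)
}

# On-axis pressure magnitude of a flat circular piston of radius a (m) with
# uniform normal velocity u0 in a lossless medium (closed form):
# |p(z)| = 2 rho c u0 |sin(k/2 (sqrt(a^2 + z^2) - z))|.
piston_on_axis <- function(z_m, a_m, u0, frequency, speed, density) {
  k <- 2 * pi * frequency / speed
  2 * density * speed * u0 * abs(sin(k / 2 * (sqrt(a_m^2 + z_m^2) - z_m)))
}

# Discrete per-axis variance (mm^2) of a non-negative 3D field about its
# centroid, on an isotropic grid.
field_variance <- function(f, voxel_size) {
  d <- dim(f)
  tot <- sum(f)
  vapply(1:3, function(a) {
    x <- (seq_len(d[a]) - 1) * voxel_size
    w <- apply(f, a, sum)
    mu <- sum(x * w) / tot
    sum((x - mu)^2 * w) / tot
  }, 0)
}

# A compact water-only voxel model and a focused source plane for solver tests.
water_model <- function(n_xy, n_z, voxel_size, frequency = 940e3) {
  uniform_model(c(n_xy, n_xy, n_z), default_material_table()$water,
                voxel_size, frequency)
}

# Table 2 derived constants reused across tests.
GEL <- default_material_table()$gelatin_70
OIL <- default_material_table()$canola_oil
ALPHA_GEL_940 <- 5.264           # Np/m at 940 kHz
Z_GEL <- 1093 * 1578.5           # 1.7253e6 Rayl
Z_OIL <- 940 * 1462              # 1.3743e6 Rayl
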