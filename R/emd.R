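#' Earth mover's distance between two non-negative 2D patterns
#'
#' Each pattern is normalized to unit total mass, and the discrete optimal
#' transport problem with Euclidean ground distance (in pixel units of the
#' input grids) is solved exactly by the transportation simplex. The result
#' is the minimal work -- mass moved times distance moved -- in pixel
#' lengths; identical patterns give 0 and on unit-mass patterns the value is
#' a metric. Patterns larger than `max_side` per axis are first downsampled
#' by mass-conserving binning (ground distances stay in original pixel
#' units).
#'
#' @param pattern_a,pattern_b non-negative matrices with positive total mass
#'   (e.g. focal-plane pressure magnitudes).
#' @param max_side maximum pattern side before binning (default 64; the exact
#'   solver cost grows quickly with the number of non-zero pixels).
#' @return EMD in pixel lengths.
#' @export
emd <- function(pattern_a, pattern_b, max_side = 64L) {
  prep <- function(x) {
    x <- as.matrix(x)
    if (any(x < 0) || any(!is.finite(x))) stop("invalid input: pattern must be non-negative and finite")
    if (sum(x) <= 0) stop("invalid input: pattern has zero mass")
    f <- ceiling(max(dim(x)) / max_side)
    list(m = if (f > 1) bin_pattern(x, f) else x, f = f)
  }
  a <- prep(pattern_a); b <- prep(pattern_b)
  pa <- a$m / sum(a$m); pb <- b$m / sum(b$m)
  ia <- which(pa > 0, arr.ind = TRUE); wa <- pa[pa > 0]
  ib <- which(pb > 0, arr.ind = TRUE); wb <- pb[pb > 0]
  # pixel-center coordinates in original pixel units (binning by f maps bin j
  # to original coordinate (j - 0.5) * f + 0.5 offset; a common shift cancels
  # in the distance)
  ca <- (ia - 0.5) * a$f
  cb <- (ib - 0.5) * b$f
  cost <- sqrt(outer(ca[, 1], cb[, 1], `-`)^2 + outer(ca[, 2], cb[, 2], `-`)^2)
  transport_simplex(wa, wb, cost)$cost
}

#' Mass-conserving binning of a 2D pattern
#'
#' Sums `factor x factor` blocks (zero-padding the trailing edge), so total
#' mass is preserved exactly.
#'
#' @param x non-negative matrix.
#' @param factor integer block size.
#' @return The binned matrix.
#' @export
bin_pattern <- function(x, factor) {
  factor <- as.integer(factor)
  d <- dim(x)
  dn <- ceiling(d / factor)
  xp <- matrix(0, dn[1] * factor, dn[2] * factor)
  xp[seq_len(d[1]), seq_len(d[2])] <- x
  a <- array(xp, c(factor, dn[1], factor, dn[2]))
  apply(a, c(2, 4), sum)
}

# Exact solver for the balanced transportation problem
#   min sum_ij cost_ij x_ij  s.t.  rowSums(x) = supply, colSums(x) = demand.
# Matrix-minimum initial basis, then MODI (u-v) pivoting on a spanning-tree
# basis. A tiny supply/demand perturbation guards against degenerate cycling;
# its effect on the optimum is O(1e-11 * max cost).
transport_simplex <- function(supply, demand, cost, tol = 1e-12,
                              max_iter = NULL) {
  m <- length(supply); n <- length(demand)
  stopifnot(nrow(cost) == m, ncol(cost) == n)
  s <- sum(supply)
  if (abs(sum(demand) - s) > 1e-9 * s) stop("unbalanced transport problem")
  demand <- demand * (s / sum(demand))
  eps <- 1e-11 * s / max(m, 1)
  supply <- supply + eps
  demand <- demand + eps * m / n

  # --- initial basic feasible solution: northwest-corner rule (always yields
  # a spanning tree of exactly m + n - 1 basic cells)
  a <- supply; b <- demand
  basis_i <- integer(m + n - 1L); basis_j <- integer(m + n - 1L)
  flow <- numeric(m + n - 1L)
  i <- 1L; j <- 1L
  for (e in seq_len(m + n - 1L)) {
    f <- min(a[i], b[j])
    basis_i[e] <- i; basis_j[e] <- j; flow[e] <- f
    a[i] <- a[i] - f; b[j] <- b[j] - f
    if (i == m && j == n) break
    if (a[i] <= b[j] && i < m) i <- i + 1L else j <- j + 1L
  }

  if (is.null(max_iter)) max_iter <- 50L * (m + n) + 1000L
  for (iter in seq_len(max_iter)) {
    nb <- length(basis_i)
    # --- duals via tree traversal (adjacency over basis arcs)
    u <- rep(NA_real_, m); v <- rep(NA_real_, n)
    u[1] <- 0
    remaining <- rep(TRUE, nb)
    repeat {
      prog <- FALSE
      for (e in which(remaining)) {
        i <- basis_i[e]; j <- basis_j[e]
        if (!is.na(u[i]) && is.na(v[j])) {
          v[j] <- cost[i, j] - u[i]; remaining[e] <- FALSE; prog <- TRUE
        } else if (is.na(u[i]) && !is.na(v[j])) {
          u[i] <- cost[i, j] - v[j]; remaining[e] <- FALSE; prog <- TRUE
        } else if (!is.na(u[i]) && !is.na(v[j])) {
          remaining[e] <- FALSE; prog <- TRUE
        }
      }
      if (!any(remaining)) break
      if (!prog) { # disconnected basis (shouldn't happen); root a new component
        e <- which(remaining)[1]
        u[basis_i[e]] <- 0
      }
    }
    # --- entering arc: most negative reduced cost
    red <- cost - outer(u, v, `+`)
    red[cbind(basis_i, basis_j)] <- 0
    ent <- which.min(red)
    if (red[ent] >= -max(1e-10, tol * max(abs(cost)))) break
    ei <- ((ent - 1L) %% m) + 1L; ej <- ((ent - 1L) %/% m) + 1L

    # --- find the unique cycle: path from row node ei to col node ej in the
    # basis tree (nodes: rows 1..m, cols m+1..m+n)
    adj <- vector("list", m + n)
    for (e in seq_len(nb)) {
      ri <- basis_i[e]; cj <- m + basis_j[e]
      adj[[ri]] <- c(adj[[ri]], e); adj[[cj]] <- c(adj[[cj]], e)
    }
    parent_edge <- rep(NA_integer_, m + n)
    parent_node <- rep(NA_integer_, m + n)
    seen <- rep(FALSE, m + n); seen[ei] <- TRUE
    queue <- ei
    target <- m + ej
    while (length(queue) && !seen[target]) {
      nd <- queue[1]; queue <- queue[-1]
      for (e in adj[[nd]]) {
        other <- if (nd <= m) m + basis_j[e] else basis_i[e]
        if (!seen[other]) {
          seen[other] <- TRUE
          parent_edge[other] <- e; parent_node[other] <- nd
          queue <- c(queue, other)
        }
      }
    }
    if (!seen[target]) stop("internal error: basis tree disconnected")
    path_edges <- integer(0)
    nd <- target
    while (nd != ei) {
      path_edges <- c(parent_edge[nd], path_edges)
      nd <- parent_node[nd]
    }
    # orientation: the entering arc (ei -> ej) carries +theta; arcs along the
    # path alternate -,+,-,... starting from the col end back to the row end
    sgn <- rep(c(-1, 1), length.out = length(path_edges))
    # path_edges runs ei -> ej; first edge leaves a row node (like entering
    # arc) so it takes -theta, alternating after
    theta_lim <- flow[path_edges[sgn == -1]]
    theta <- min(theta_lim)
    leave_rel <- which(sgn == -1)[which.min(theta_lim)]
    leave <- path_edges[leave_rel]
    flow[path_edges] <- flow[path_edges] + sgn * theta
    basis_i[leave] <- ei; basis_j[leave] <- ej; flow[leave] <- theta
    if (iter == max_iter)
      warning("transport simplex hit the iteration cap; result may be suboptimal")
  }
  x <- matrix(0, m, n)
  x[cbind(basis_i, basis_j)] <- flow
  list(cost = sum(cost[cbind(basis_i, basis_j)] * flow), plan = x,
       u = u, v = v)
}
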