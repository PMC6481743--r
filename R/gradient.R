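# Structured-grid differential operators and interpolation for tube meshes.
#
# The polar-cylindrical node layout makes directional finite differences
# natural: second-order central differences along the circumferential,
# interior radial, and interior axial coordinate lines (each equivalent to a
# least-squares linear fit along that line), with two-point one-sided
# differences at the wall ring and the end layers. Cartesian gradients
# follow from the orthonormal local frame (e_r, e_theta, e_z). The gradient
# at the axis nodes comes from a closed-form least-squares linear fit over
# the first ring.

# reshape a nodal scalar into (ring array [n_circ, n_radial, n_layers],
# center vector [n_layers])
.split_nodal <- function(mesh, u) {
  idx <- .ring_index(mesh)
  list(A = array(u[idx$ring], dim = c(mesh$n_circ, mesh$n_radial, mesh$n_layers)),
       c = u[idx$center])
}

#' Nodal gradient of a scalar field on a tube mesh
#'
#' @param mesh A `tube_mesh`.
#' @param u Numeric vector of nodal values.
#' @return N x 3 matrix of Cartesian gradient components.
#' @keywords internal
grad_nodal <- function(mesh, u) {
  nc <- mesh$n_circ; nr <- mesh$n_radial; nl <- mesh$n_layers
  sp <- .split_nodal(mesh, u)
  A <- sp$A; cn <- sp$c
  dr <- mesh$dr; dth <- mesh$dtheta; dz <- mesh$dz

  kp <- c(2:nc, 1L); km <- c(nc, 1:(nc - 1L))
  dA_dth <- (A[kp, , , drop = FALSE] - A[km, , , drop = FALSE]) / (2 * dth)

  dA_dr <- array(0, dim = dim(A))
  # ring 1: central using the center node (value independent of theta)
  if (nr >= 2L) {
    cen <- aperm(array(cn, dim = c(nl, nc)), c(2, 1))  # [nc, nl]
    dA_dr[, 1L, ] <- (A[, 2L, ] - cen) / (2 * dr)
    if (nr >= 3L)
      dA_dr[, 2:(nr - 1L), ] <-
        (A[, 3:nr, , drop = FALSE] - A[, 1:(nr - 2L), , drop = FALSE]) / (2 * dr)
    # wall ring: one-sided, consistent with a near-wall linear reconstruction
    dA_dr[, nr, ] <- (A[, nr, ] - A[, nr - 1L, ]) / dr
  }

  dA_dz <- array(0, dim = dim(A))
  dA_dz[, , 2:(nl - 1L)] <-
    (A[, , 3:nl, drop = FALSE] - A[, , 1:(nl - 2L), drop = FALSE]) / (2 * dz)
  dA_dz[, , 1L] <- (A[, , 2L] - A[, , 1L]) / dz
  dA_dz[, , nl] <- (A[, , nl] - A[, , nl - 1L]) / dz

  theta <- mesh$dtheta * (seq_len(nc) - 1L)
  r <- mesh$dr * seq_len(nr)
  cth <- array(cos(theta), dim = dim(A))
  sth <- array(sin(theta), dim = dim(A))
  rinv <- array(rep(1 / r, each = nc), dim = dim(A))

  gx_ring <- cth * dA_dr - sth * rinv * dA_dth
  gy_ring <- sth * dA_dr + cth * rinv * dA_dth
  gz_ring <- dA_dz

  # center nodes: LS linear fit over ring 1 -> Fourier projection
  ring1 <- A[, 1L, , drop = FALSE]            # [nc, 1, nl]
  gx_c <- colSums(ring1[, 1L, , drop = FALSE] * cos(theta)) * 2 / (nc * dr)
  gy_c <- colSums(ring1[, 1L, , drop = FALSE] * sin(theta)) * 2 / (nc * dr)
  gz_c <- numeric(nl)
  gz_c[2:(nl - 1L)] <- (cn[3:nl] - cn[1:(nl - 2L)]) / (2 * dz)
  gz_c[1L] <- (cn[2L] - cn[1L]) / dz
  gz_c[nl] <- (cn[nl] - cn[nl - 1L]) / dz

  G <- matrix(0, nrow = nrow(mesh$node_positions), ncol = 3)
  idx <- .ring_index(mesh)
  G[idx$ring, 1] <- as.vector(gx_ring)
  G[idx$ring, 2] <- as.vector(gy_ring)
  G[idx$ring, 3] <- as.vector(gz_ring)
  G[idx$center, 1] <- as.vector(gx_c)
  G[idx$center, 2] <- as.vector(gy_c)
  G[idx$center, 3] <- gz_c
  G
}

# local polar coordinates of arbitrary points
.local_coords <- function(mesh, pts) {
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  th <- atan2(pts[, 2], pts[, 1]) %% (2 * pi)
  list(r = r, theta = th, z = pts[, 3])
}

# trilinear interpolation of nodal values (N x m matrix) at points (p x 3);
# radial between center (ring 0) and rings, periodic in theta, clamped in z
.interp_nodal <- function(mesh, values, pts) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  lc <- .local_coords(mesh, pts)
  nr <- mesh$n_radial; nc <- mesh$n_circ; nl <- mesh$n_layers; npl <- mesh$npl

  fr <- pmin(pmax(lc$r / mesh$dr, 0), nr)
  j0 <- pmin(floor(fr), nr - 1L); ar <- fr - j0
  ft <- (lc$theta / mesh$dtheta) %% nc
  k0 <- pmin(floor(ft), nc - 1L); at <- ft - k0
  fz <- pmin(pmax(lc$z / mesh$dz, 0), nl - 1L)
  i0 <- pmin(floor(fz), nl - 2L); az <- fz - i0

  nidx <- function(i, j, k) {
    # 0-based i (layer), j (ring; 0 = center), k (circ)
    ifelse(j == 0L, i * npl + 1L, i * npl + 1L + (j - 1L) * nc + (k %% nc) + 1L)
  }
  out <- matrix(0, nrow = nrow(pts), ncol = ncol(values))
  for (dj in 0:1) for (dk in 0:1) for (di in 0:1) {
    j <- j0 + dj
    wgt <- (if (dj == 1) ar else 1 - ar) *
           (if (dk == 1) at else 1 - at) *
           (if (di == 1) az else 1 - az)
    idx <- nidx(i0 + di, j, k0 + dk)
    out <- out + wgt * values[idx, , drop = FALSE]
  }
  out
}

# periodic-in-time interpolation weights over field times spanning [0, T)
.time_weights <- function(times, period, t) {
  nt <- length(times)
  if (nt == 1L) return(list(i0 = 1L, i1 = 1L, a = 0))
  tt <- t %% period
  i0 <- findInterval(tt, times)
  i0[i0 < 1L] <- nt                      # before first sample: wrap
  i1 <- ifelse(i0 == nt, 1L, i0 + 1L)
  t0 <- times[i0]
  dt <- ifelse(i0 == nt, period - times[nt] + times[1], times[i1] - t0)
  a <- ((tt - t0) %% period) / dt
  list(i0 = i0, i1 = i1, a = a)
}
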