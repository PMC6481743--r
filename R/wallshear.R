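# Wall shear stress and its derived indices (TAWSS, OSI, spatiotemporal
# maps, inter-variant difference maps).

#' Wall shear stress vectors from a velocity field
#'
#' Viscous traction at the wall: `tau_w` is the tangential part of
#' `mu (grad v + grad v^T) . n_hat` evaluated at each wall-face centroid.
#' Velocity gradients are reconstructed on the structured grid (directional
#' finite differences with a one-sided near-wall radial stencil) at the
#' wall nodes; face values average the four face nodes and are projected
#' onto the face tangent plane.
#'
#' @param field A `tv_field` on a mesh with wall faces.
#' @param fluid A `fluid_properties`.
#' @return An object of class `wss_field`: `tau` `[n_faces, 3, n_times]`,
#'   face centroids, unit normals, areas, regions, `times`, `period`.
#' @export
compute_wss <- function(field, fluid = fluid_properties()) {
  mesh <- field$mesh
  mu <- fluid$dynamic_viscosity
  nt <- dim(field$velocity)[3]
  nf <- nrow(mesh$wall_faces)
  tau <- array(0, dim = c(nf, 3, nt))
  N <- mesh$wall_face_normals
  for (m in seq_len(nt)) {
    V <- field$velocity[, , m]
    Gx <- grad_nodal(mesh, V[, 1])
    Gy <- grad_nodal(mesh, V[, 2])
    Gz <- grad_nodal(mesh, V[, 3])
    # traction t = mu (G + G^T) n at each wall node, averaged per face
    tn <- matrix(0, nf, 3)
    for (corner in 1:4) {
      idx <- mesh$wall_faces[, corner]
      # use the face normal for all four corners (planar chord face)
      gxx <- Gx[idx, , drop = FALSE]
      gyy <- Gy[idx, , drop = FALSE]
      gzz <- Gz[idx, , drop = FALSE]
      # S n where S = G + G^T, with G[i, j] = d v_i / d x_j
      sx <- (2 * gxx[, 1]) * N[, 1] + (gxx[, 2] + gyy[, 1]) * N[, 2] +
        (gxx[, 3] + gzz[, 1]) * N[, 3]
      sy <- (gyy[, 1] + gxx[, 2]) * N[, 1] + (2 * gyy[, 2]) * N[, 2] +
        (gyy[, 3] + gzz[, 2]) * N[, 3]
      sz <- (gzz[, 1] + gxx[, 3]) * N[, 1] + (gzz[, 2] + gyy[, 3]) * N[, 2] +
        (2 * gzz[, 3]) * N[, 3]
      tn <- tn + cbind(sx, sy, sz) / 4
    }
    tn <- mu * tn
    # tangential projection
    tn_n <- rowSums(tn * N)
    tau[, , m] <- tn - tn_n * N
  }
  structure(list(tau = tau,
                 centroids = mesh$wall_face_centroids,
                 normals = N,
                 areas = mesh$wall_face_areas,
                 regions = mesh$wall_face_regions,
                 times = field$times, period = field$period,
                 mesh = mesh),
            class = "wss_field")
}

# periodic trapezoid weights over sample times spanning [0, T)
.periodic_trapezoid_weights <- function(times, period) {
  n <- length(times)
  if (n == 1L) return(period)
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  ((times[ip] - times[im]) %% period) / 2
}

# area-weighted interpolated quantile (midpoint positions)
weighted_quantile <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  pos <- (cw - w / 2) / sum(w)
  stats::approx(pos, x, xout = p, rule = 2)$y
}

#' TAWSS, OSI and surface summaries from a WSS field
#'
#' Per face: `TAWSS = (1/T) int |tau| dt` and
#' `OSI = 0.5 (1 - |int tau dt| / int |tau| dt)` (0 where the magnitude
#' integral vanishes), with periodic trapezoid time integrals over the
#' stored phases. Surface summaries are area-weighted: whole-surface mean
#' TAWSS and OSI, regional mean TAWSS (AAo, AA, DAo), and an area-weighted
#' interpolated 99th-percentile TAWSS (used instead of the raw maximum to
#' exclude spurious extremes).
#'
#' @param wss A `wss_field`.
#' @param T Cycle duration (s); must match the field period.
#' @return An object of class `wss_indices`.
#' @export
compute_indices <- function(wss, T = wss$period) {
  stopifnot(inherits(wss, "wss_field"))
  if (abs(T - wss$period) > 1e-9 * T)
    stop("T does not match the sample period of the WSS field")
  nt <- dim(wss$tau)[3]
  wt <- .periodic_trapezoid_weights(wss$times, T)
  mag <- sqrt(wss$tau[, 1, , drop = FALSE]^2 + wss$tau[, 2, , drop = FALSE]^2 +
                wss$tau[, 3, , drop = FALSE]^2)[, 1, ]
  mag <- matrix(mag, ncol = nt)
  int_mag <- as.vector(mag %*% wt)
  int_vec <- vapply(1:3, function(d)
    as.vector(matrix(wss$tau[, d, ], ncol = nt) %*% wt), numeric(nrow(mag)))
  tawss <- int_mag / T
  osi <- ifelse(int_mag > 0,
                0.5 * (1 - sqrt(rowSums(int_vec^2)) / int_mag), 0)
  osi <- pmin(pmax(osi, 0), 0.5)

  A <- wss$areas
  regs <- c("AAo", "AA", "DAo")
  reg_mean <- vapply(regs, function(rg) {
    sel <- wss$regions == rg
    if (!any(sel)) return(NA_real_)
    sum(A[sel] * tawss[sel]) / sum(A[sel])
  }, numeric(1))
  structure(list(
    tawss = tawss, osi = osi, areas = A, regions = wss$regions,
    mean_tawss = sum(A * tawss) / sum(A),
    p99_tawss = weighted_quantile(tawss, A, 0.99),
    regional_mean_tawss = reg_mean,
    mean_osi = sum(A * osi) / sum(A)
  ), class = "wss_indices")
}

#' @export
print.wss_indices <- function(x, ...) {
  cat(sprintf("WSS indices over %d faces:\n", length(x$tawss)))
  cat(sprintf("  TAWSS: mean %.3g Pa, 99th prc %.3g Pa; regions AAo %.3g / AA %.3g / DAo %.3g Pa\n",
              x$mean_tawss, x$p99_tawss, x$regional_mean_tawss["AAo"],
              x$regional_mean_tawss["AA"], x$regional_mean_tawss["DAo"]))
  cat(sprintf("  OSI: mean %.3g\n", x$mean_osi))
  invisible(x)
}

#' Difference maps between WSS index sets
#'
#' Per-face absolute differences in TAWSS and OSI, plus percent differences
#' of the area-weighted summaries, signed as
#' `100 (other - reference) / reference`. Zero-reference summary cells are
#' reported as 0 when the other variant is also (numerically) zero, and as
#' `NA` otherwise.
#'
#' @param reference A `wss_indices` (the benchmark variant).
#' @param other A `wss_indices` on the same faces.
#' @return List with `abs_diff_tawss`, `abs_diff_osi` (per face) and a
#'   `percent` named vector (mean/p99/AAo/AA/DAo TAWSS, mean OSI).
#' @export
diff_maps <- function(reference, other) {
  stopifnot(inherits(reference, "wss_indices"), inherits(other, "wss_indices"))
  if (length(reference$tawss) != length(other$tawss) ||
      max(abs(reference$areas - other$areas)) > 1e-12)
    stop("WSS index sets live on different meshes")
  pct <- function(ref, oth) {
    if (!is.finite(ref)) return(NA_real_)
    if (abs(ref) < 1e-300) {
      if (abs(oth) < 1e-12) return(0) else return(NA_real_)
    }
    100 * (oth - ref) / ref
  }
  percent <- c(
    mean_tawss = pct(reference$mean_tawss, other$mean_tawss),
    p99_tawss = pct(reference$p99_tawss, other$p99_tawss),
    AAo_tawss = pct(reference$regional_mean_tawss["AAo"],
                    other$regional_mean_tawss["AAo"]),
    AA_tawss = pct(reference$regional_mean_tawss["AA"],
                   other$regional_mean_tawss["AA"]),
    DAo_tawss = pct(reference$regional_mean_tawss["DAo"],
                    other$regional_mean_tawss["DAo"]),
    mean_osi = pct(reference$mean_osi, other$mean_osi))
  names(percent) <- c("mean_tawss", "p99_tawss", "AAo_tawss", "AA_tawss",
                      "DAo_tawss", "mean_osi")
  list(abs_diff_tawss = abs(other$tawss - reference$tawss),
       abs_diff_osi = abs(other$osi - reference$osi),
       percent = percent)
}

#' Unwrapped spatiotemporal WSS map at an analysis plane
#'
#' Extracts the ring of wall faces cut by a transverse plane at axial
#' position `s_plane`, orders them by angle about the contour centroid,
#' normalizes arc length to `[0, 1]`, and tabulates `|tau_w|` per time
#' point.
#'
#' @param wss A `wss_field`.
#' @param s_plane Axial position of the analysis plane (m).
#' @return An object of class `spatiotemporal_map`: `coordinate` (normalized
#'   circumferential position), `times`, and `magnitude`
#'   `[n_circumferential, n_times]` (Pa).
#' @export
spatiotemporal_map <- function(wss, s_plane) {
  mesh <- wss$mesh
  if (s_plane < 0 || s_plane > mesh$length)
    stop("analysis plane at s = ", s_plane,
         " m does not intersect the wall in a single closed contour")
  # faces of the axial face row containing s_plane
  row_i <- min(max(ceiling(s_plane / mesh$dz), 1L), mesh$n_axial)
  sel <- which(abs(wss$centroids[, 3] - (row_i - 0.5) * mesh$dz) < mesh$dz / 4)
  cen <- wss$centroids[sel, , drop = FALSE]
  c0 <- colMeans(cen)
  ang <- atan2(cen[, 2] - c0[2], cen[, 1] - c0[1]) %% (2 * pi)
  o <- order(ang)
  sel <- sel[o]
  nt <- dim(wss$tau)[3]
  magn <- sqrt(wss$tau[sel, 1, , drop = FALSE]^2 +
                 wss$tau[sel, 2, , drop = FALSE]^2 +
                 wss$tau[sel, 3, , drop = FALSE]^2)
  magn <- matrix(magn, ncol = nt)
  coord <- (seq_along(sel) - 0.5) / length(sel)
  structure(list(coordinate = coord, times = wss$times, magnitude = magn,
                 s_plane = s_plane),
            class = "spatiotemporal_map")
}
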