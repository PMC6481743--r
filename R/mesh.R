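#' Blood-like fluid properties
#'
#' Constant-property Newtonian fluid. Defaults are the standard blood
#' analogue used in large-vessel hemodynamics: dynamic viscosity
#' 4e-3 Pa s and density 1060 kg/m^3.
#'
#' @param dynamic_viscosity Dynamic viscosity in Pa s.
#' @param density Density in kg/m^3.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(dynamic_viscosity = 4e-3, density = 1060) {
  if (!is.finite(dynamic_viscosity) || dynamic_viscosity <= 0)
    stop("dynamic_viscosity must be strictly positive")
  if (!is.finite(density) || density <= 0)
    stop("density must be strictly positive")
  structure(list(dynamic_viscosity = dynamic_viscosity, density = density),
            class = "fluid_properties")
}

#' Structured straight-tube mesh
#'
#' Builds a structured hexahedral discretization of a straight circular tube
#' of radius `radius` and length `length`, aligned with the z axis, with the
#' inlet at z = 0 and the outlet at z = `length`. Nodes are laid out on
#' polar cross-section grids (one center node plus `n_radial` rings of
#' `n_circ` nodes) repeated over `n_axial + 1` axial layers. The lateral
#' wall is tiled with quadrilateral faces carrying outward unit normals.
#'
#' The tube is a geometric stand-in for a thoracic aorta: its arc length is
#' partitioned into three contiguous regions labelled `AAo`, `AA` and `DAo`
#' (ascending aorta, arch, descending aorta) by `region_fractions`.
#'
#' Cross-section quadrature weights (exact annulus areas, summing to
#' pi R^2) are attached for flux and surface integrals, and per-node
#' volumes for volume-weighted statistics.
#'
#' @param radius Tube radius (m).
#' @param length Tube length (m).
#' @param n_radial Number of radial rings (>= 2).
#' @param n_circ Number of circumferential divisions (>= 2).
#' @param n_axial Number of axial cell layers (>= 2).
#' @param region_fractions Length-3 positive vector of arc-length fractions
#'   for the AAo/AA/DAo partition; normalized to sum to 1.
#' @return An object of class `tube_mesh`.
#' @export
make_straight_tube_mesh <- function(radius, length, n_radial = 12, n_circ = 32,
                                    n_axial = 24,
                                    region_fractions = c(1, 1, 1) / 3) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  if (!is.finite(length) || length <= 0) stop("length must be > 0")
  counts <- c(n_radial = n_radial, n_circ = n_circ, n_axial = n_axial)
  if (any(counts != round(counts)) || any(counts < 2))
    stop("n_radial, n_circ and n_axial must be integer counts >= 2 ",
         "(got ", paste(counts, collapse = ", "), ")")
  if (length(region_fractions) != 3L || any(region_fractions <= 0))
    stop("region_fractions must be 3 positive fractions")
  region_fractions <- region_fractions / sum(region_fractions)

  dr <- radius / n_radial
  dth <- 2 * pi / n_circ
  dz <- length / n_axial
  n_layers <- n_axial + 1L
  npl <- 1L + n_radial * n_circ           # nodes per layer (center + rings)

  theta <- dth * (seq_len(n_circ) - 1L)
  r <- dr * seq_len(n_radial)

  # node positions, layer-major; within a layer: center, then rings
  # (ring index j slow, circumferential index k fast)
  xy_ring <- cbind(as.vector(outer(cos(theta), r)),
                   as.vector(outer(sin(theta), r)))
  layer_xy <- rbind(c(0, 0), xy_ring)
  nodes <- matrix(0, nrow = npl * n_layers, ncol = 3)
  for (i in seq_len(n_layers)) {
    rows <- (i - 1L) * npl + seq_len(npl)
    nodes[rows, 1:2] <- layer_xy
    nodes[rows, 3] <- (i - 1L) * dz
  }

  nidx <- function(i, j, k) {
    # 1-based layer i, ring j (0 = center), circumferential k (1..n_circ);
    # arguments recycle to a common length
    n <- max(length(i), length(j), length(k))
    i <- rep_len(i, n); j <- rep_len(j, n); k <- rep_len(k, n)
    ifelse(j == 0L, (i - 1L) * npl + 1L,
           (i - 1L) * npl + 1L + (j - 1L) * n_circ + k)
  }

  # hexahedral cells between consecutive layers; innermost ring stored as
  # collapsed hexes (center node repeated) for completeness
  kk <- seq_len(n_circ)
  kp <- c(kk[-1L], 1L)
  cell_list <- vector("list", n_axial)
  for (i in seq_len(n_axial)) {
    blocks <- vector("list", n_radial)
    blocks[[1L]] <- cbind(nidx(i, 0L, kk), nidx(i, 0L, kk),
                          nidx(i, 1L, kk), nidx(i, 1L, kp),
                          nidx(i + 1L, 0L, kk), nidx(i + 1L, 0L, kk),
                          nidx(i + 1L, 1L, kk), nidx(i + 1L, 1L, kp))
    if (n_radial > 1L) {
      for (j in seq_len(n_radial - 1L)) {
        blocks[[j + 1L]] <- cbind(nidx(i, j, kk), nidx(i, j, kp),
                                  nidx(i, j + 1L, kp), nidx(i, j + 1L, kk),
                                  nidx(i + 1L, j, kk), nidx(i + 1L, j, kp),
                                  nidx(i + 1L, j + 1L, kp), nidx(i + 1L, j + 1L, kk))
      }
    }
    cell_list[[i]] <- do.call(rbind, blocks)
  }
  cells <- do.call(rbind, cell_list)

  # lateral wall faces: chord quads between layers at ring n_radial
  ii <- rep(seq_len(n_axial), each = n_circ)
  kk2 <- rep(seq_len(n_circ), times = n_axial)
  kp2 <- ifelse(kk2 == n_circ, 1L, kk2 + 1L)
  wall_faces <- cbind(nidx(ii, n_radial, kk2), nidx(ii, n_radial, kp2),
                      nidx(ii + 1L, n_radial, kp2), nidx(ii + 1L, n_radial, kk2))
  th_mid <- dth * (kk2 - 1L) + dth / 2
  wall_face_normals <- cbind(cos(th_mid), sin(th_mid), 0)
  chord <- 2 * radius * sin(dth / 2)
  wall_face_areas <- rep(chord * dz, n_circ * n_axial)
  wall_face_centroids <- cbind(radius * cos(dth / 2) * cos(th_mid),
                               radius * cos(dth / 2) * sin(th_mid),
                               (ii - 0.5) * dz)

  # exact annulus-area quadrature weights over a cross-section (sum = pi R^2)
  w <- numeric(npl)
  w[1L] <- pi * (dr / 2)^2
  for (j in seq_len(n_radial)) {
    r_in <- r[j] - dr / 2
    r_out <- min(r[j] + dr / 2, radius)
    w[1L + (j - 1L) * n_circ + seq_len(n_circ)] <- pi * (r_out^2 - r_in^2) / n_circ
  }

  # axial trapezoid weights -> node volumes
  wz <- rep(dz, n_layers); wz[c(1L, n_layers)] <- dz / 2
  node_volumes <- as.vector(outer(w, wz))

  s <- nodes[, 3]
  breaks <- length * cumsum(region_fractions)[1:2]
  region_of <- function(sv) {
    out <- rep("DAo", length(sv))
    out[sv < breaks[2]] <- "AA"
    out[sv < breaks[1]] <- "AAo"
    out
  }

  structure(list(
    radius = radius, length = length,
    n_radial = n_radial, n_circ = n_circ, n_axial = n_axial,
    dr = dr, dtheta = dth, dz = dz, n_layers = n_layers, npl = npl,
    node_positions = nodes,
    cells = cells,
    wall_faces = wall_faces,
    wall_face_normals = wall_face_normals,
    wall_face_areas = wall_face_areas,
    wall_face_centroids = wall_face_centroids,
    wall_face_regions = region_of(wall_face_centroids[, 3]),
    inlet_patch = seq_len(npl),
    outlet_patch = (n_layers - 1L) * npl + seq_len(npl),
    inlet_normal = c(0, 0, 1),          # into the domain
    outlet_normal = c(0, 0, 1),
    cross_section_weights = w,
    inlet_area = sum(w),
    node_volumes = node_volumes,
    centerline_s = s,
    region_labels = region_of(s),
    region_fractions = region_fractions
  ), class = "tube_mesh")
}

#' @export
print.tube_mesh <- function(x, ...) {
  cat("Straight-tube mesh: R =", x$radius, "m, L =", x$length, "m\n")
  cat("  resolution:", x$n_radial, "radial x", x$n_circ, "circumferential x",
      x$n_axial, "axial;", nrow(x$node_positions), "nodes,",
      nrow(x$wall_faces), "wall faces\n")
  cat("  regions:", paste(sprintf("%s %.0f%%", c("AAo", "AA", "DAo"),
                                  100 * x$region_fractions), collapse = ", "), "\n")
  invisible(x)
}

# radial/circumferential/axial indices of every ring node, layer-major
.ring_index <- function(mesh) {
  nrg <- mesh$n_radial * mesh$n_circ
  list(center = (seq_len(mesh$n_layers) - 1L) * mesh$npl + 1L,
       ring = as.integer(as.vector(vapply(seq_len(mesh$n_layers), function(i) {
         (i - 1L) * mesh$npl + 1L + seq_len(nrg)
       }, numeric(nrg)))))
}

#' Integrated normal flux through the inlet patch
#'
#' Quadrature (exact annulus-area weights) of the velocity component along
#' the inward inlet normal over the inlet cross-section.
#'
#' @param mesh A `tube_mesh`.
#' @param velocity Either an N x 3 matrix of nodal velocities or an
#'   n_inlet x 3 matrix restricted to the inlet patch.
#' @return Volumetric flux (m^3/s).
#' @export
inlet_flux <- function(mesh, velocity) {
  if (nrow(velocity) == nrow(mesh$node_positions))
    velocity <- velocity[mesh$inlet_patch, , drop = FALSE]
  if (nrow(velocity) != mesh$npl)
    stop("velocity must cover all nodes or exactly the inlet patch")
  sum(mesh$cross_section_weights * (velocity %*% mesh$inlet_normal))
}
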