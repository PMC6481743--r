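# Emulated phase-contrast MRI plane acquisition.

#' Acquisition plane specification
#'
#' Geometry of a PC-MRI acquisition plane: origin, two orthonormal in-plane
#' axes and the implied unit normal (`u x v`).
#'
#' @param origin Plane origin (3-vector, m).
#' @param axis_u,axis_v In-plane axis directions (3-vectors); orthonormalized
#'   internally.
#' @return An object of class `plane_spec`.
#' @export
plane_spec <- function(origin = c(0, 0, 0), axis_u = c(1, 0, 0),
                       axis_v = c(0, 1, 0)) {
  u <- axis_u / sqrt(sum(axis_u^2))
  v <- axis_v - sum(axis_v * u) * u
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("axis_v must not be collinear with axis_u")
  v <- v / nv
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  structure(list(origin = origin, axis_u = u, axis_v = v, normal = n),
            class = "plane_spec")
}

# wrap velocities into [-venc, venc): values beyond the encoding limit
# alias by +/- 2 venc, as in phase-contrast encoding; in-range values are
# returned bit-identical (idempotent)
.alias_wrap <- function(v, venc) {
  out <- v >= venc | v < -venc
  v[out] <- ((v[out] + venc) %% (2 * venc)) - venc
  v
}

#' Emulated PC-MRI acquisition of a velocity field on a plane
#'
#' Samples a velocity field on a regular pixel grid over an acquisition
#' plane. Each pixel value is the field at the pixel center, averaged
#' across the slab thickness with 5-point Gauss-Legendre quadrature along
#' the plane normal, re-expressed as components along the two in-plane axes
#' and the normal. Optional zero-mean Gaussian noise is added per component
#' per pixel per phase, and components beyond the velocity-encoding limit
#' wrap by +/- 2 VENC (aliasing). The lumen mask marks pixel centers inside
#' the vessel cross-section.
#'
#' @param field A `tv_field`.
#' @param plane A `plane_spec`. Default: transverse plane at the inlet.
#' @param pixel_size_mm In-plane pixel size (mm); default 1.4 (typical
#'   PC-MRI in-plane resolution).
#' @param slab_thickness_mm Slab thickness (mm); default 10.
#' @param phases Acquisition phase times (s); default the field's stored
#'   times.
#' @param venc Velocity-encoding limit (m/s), scalar or per-component
#'   length-3 vector; `NULL` (default) sets each component to 1.1 times its
#'   noise-free peak over the lumen, i.e. 10% above the expected peak.
#' @param noise_sd Noise standard deviation (m/s); `NULL` (default) gives
#'   `noise_frac` of the largest VENC, `0` disables noise.
#' @param noise_frac Noise standard deviation as a fraction of the largest
#'   VENC, used when `noise_sd` is `NULL`.
#' @param seed Integer seed for the noise stream.
#' @param grid_margin_mm Extra margin of pixels beyond the lumen (mm).
#' @return An object of class `plane_velocity_map` with per-pixel component
#'   arrays `vel_u`, `vel_v`, `vel_n` of dimension `[nu, nv, n_phases]`,
#'   pixel-center coordinates, lumen mask, VENC and provenance.
#' @export
acquire_plane <- function(field, plane = NULL, pixel_size_mm = 1.4,
                          slab_thickness_mm = 10, phases = NULL, venc = NULL,
                          noise_sd = NULL, noise_frac = 0.05, seed = 1L,
                          grid_margin_mm = 3) {
  mesh <- field$mesh
  if (is.null(plane)) plane <- plane_spec(origin = c(0, 0, 0))
  if (is.null(phases)) phases <- field$times
  px <- pixel_size_mm * 1e-3
  slab <- slab_thickness_mm * 1e-3

  # the plane must intersect the mesh interior
  s0 <- sum((plane$origin - c(0, 0, 0)) * c(0, 0, 1))
  if (s0 < -slab / 2 - 1e-9 || s0 > mesh$length + slab / 2 + 1e-9)
    stop("acquisition plane does not intersect the mesh interior")

  half <- mesh$radius + grid_margin_mm * 1e-3
  n_u <- ceiling(2 * half / px)
  u_coords <- (seq_len(n_u) - (n_u + 1) / 2) * px
  v_coords <- u_coords
  n_v <- n_u

  centers_u <- rep(u_coords, times = n_v)
  centers_v <- rep(v_coords, each = n_u)
  P0 <- cbind(plane$origin[1] + centers_u * plane$axis_u[1] + centers_v * plane$axis_v[1],
              plane$origin[2] + centers_u * plane$axis_u[2] + centers_v * plane$axis_v[2],
              plane$origin[3] + centers_u * plane$axis_u[3] + centers_v * plane$axis_v[3])

  # lumen mask: pixel center inside the tube cross-section
  rr <- sqrt(P0[, 1]^2 + P0[, 2]^2)
  mask <- matrix(rr <= mesh$radius, nrow = n_u, ncol = n_v)
  if (!any(mask)) stop("acquisition plane does not overlap the lumen")

  # 5-point Gauss-Legendre nodes/weights on [-1, 1]
  gl_x <- c(-0.9061798459386640, -0.5384693101056831, 0,
            0.5384693101056831, 0.9061798459386640)
  gl_w <- c(0.2369268850561891, 0.4786286704993665, 0.5688888888888889,
            0.4786286704993665, 0.2369268850561891)

  nph <- length(phases)
  vel_u <- array(0, dim = c(n_u, n_v, nph))
  vel_v <- vel_u; vel_n <- vel_u
  for (m in seq_len(nph)) {
    acc <- matrix(0, nrow = nrow(P0), ncol = 3)
    if (slab > 0) {
      for (g in seq_along(gl_x)) {
        Pg <- P0 + (slab / 2) * gl_x[g] *
          matrix(plane$normal, nrow = nrow(P0), ncol = 3, byrow = TRUE)
        acc <- acc + (gl_w[g] / 2) * field_eval(field, Pg, phases[m])
      }
    } else {
      acc <- field_eval(field, P0, phases[m])
    }
    vel_u[, , m] <- matrix(acc %*% plane$axis_u, n_u, n_v)
    vel_v[, , m] <- matrix(acc %*% plane$axis_v, n_u, n_v)
    vel_n[, , m] <- matrix(acc %*% plane$normal, n_u, n_v)
  }

  # VENC: 10% above the noise-free peak over the lumen, per component
  mask3 <- array(mask, dim = c(n_u, n_v, nph))
  peak <- c(max(abs(vel_u[mask3]), 0), max(abs(vel_v[mask3]), 0),
            max(abs(vel_n[mask3]), 0))
  if (is.null(venc)) venc <- pmax(1.1 * peak, 1e-6)
  if (length(venc) == 1L) venc <- rep(venc, 3)
  if (is.null(noise_sd)) noise_sd <- noise_frac * max(venc)

  if (noise_sd > 0) {
    set.seed(seed)
    vel_u <- vel_u + array(stats::rnorm(length(vel_u), 0, noise_sd), dim = dim(vel_u))
    vel_v <- vel_v + array(stats::rnorm(length(vel_v), 0, noise_sd), dim = dim(vel_v))
    vel_n <- vel_n + array(stats::rnorm(length(vel_n), 0, noise_sd), dim = dim(vel_n))
  }
  vel_u <- .alias_wrap(vel_u, venc[1])
  vel_v <- .alias_wrap(vel_v, venc[2])
  vel_n <- .alias_wrap(vel_n, venc[3])

  structure(list(
    n_u = n_u, n_v = n_v, pixel_size_mm = pixel_size_mm,
    slab_thickness_mm = slab_thickness_mm,
    u_coords = u_coords, v_coords = v_coords,
    plane = plane, phases = phases, period = field$period,
    vel_u = vel_u, vel_v = vel_v, vel_n = vel_n,
    lumen_mask = mask, venc = venc, noise_sd = noise_sd, seed = seed
  ), class = "plane_velocity_map")
}

#' @export
print.plane_velocity_map <- function(x, ...) {
  cat(sprintf("PC-MRI-like plane map: %d x %d pixels (%.2f mm), slab %.1f mm, %d phases\n",
              x$n_u, x$n_v, x$pixel_size_mm, x$slab_thickness_mm,
              length(x$phases)))
  cat(sprintf("  lumen pixels: %d; VENC (m/s): %s; noise sd: %.3g m/s\n",
              sum(x$lumen_mask), paste(signif(x$venc, 3), collapse = "/"),
              x$noise_sd))
  invisible(x)
}
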