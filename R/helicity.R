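# Helical-flow descriptors: vorticity, helicity density, local normalized
# helicity, thresholded-region volumes, and the Lagrangian helicity flow
# index from particle traces.

#' Helicity density and local normalized helicity
#'
#' Per node and time point: vorticity `omega = curl v` (same structured
#' gradient reconstruction as the wall-shear module), helicity density
#' `Hk = v . omega` (m/s^2), and local normalized helicity
#' `LNH = Hk / (|v| |omega|)` in `[-1, 1]`, set to 0 wherever `|v|` or
#' `|omega|` vanishes.
#'
#' @param field A `tv_field`.
#' @return An object of class `helicity_field`: `omega` `[N, 3, nt]`,
#'   `hk` and `lnh` `[N, nt]`, the mesh, times and period.
#' @export
compute_helicity <- function(field) {
  mesh <- field$mesh
  nt <- dim(field$velocity)[3]
  n <- nrow(mesh$node_positions)
  omega <- array(0, dim = c(n, 3, nt))
  hk <- matrix(0, n, nt)
  lnh <- matrix(0, n, nt)
  for (m in seq_len(nt)) {
    V <- field$velocity[, , m]
    Gx <- grad_nodal(mesh, V[, 1])
    Gy <- grad_nodal(mesh, V[, 2])
    Gz <- grad_nodal(mesh, V[, 3])
    om <- cbind(Gz[, 2] - Gy[, 3],
                Gx[, 3] - Gz[, 1],
                Gy[, 1] - Gx[, 2])
    omega[, , m] <- om
    h <- rowSums(V * om)
    hk[, m] <- h
    vmag <- sqrt(rowSums(V^2))
    omag <- sqrt(rowSums(om^2))
    den <- vmag * omag
    lnh[, m] <- ifelse(den > 1e-300, pmin(pmax(h / den, -1), 1), 0)
  }
  structure(list(omega = omega, hk = hk, lnh = lnh, mesh = mesh,
                 times = field$times, period = field$period),
            class = "helicity_field")
}

#' Volume fractions above a helicity-density threshold
#'
#' Node-volume-weighted fraction of each region (and of the whole domain)
#' with `Hk >= theta` (positive, clockwise helical flow) and `Hk <= -theta`
#' (negative, anti-clockwise), per time point.
#'
#' @param hel A `helicity_field`.
#' @param theta Threshold (m/s^2), > 0. The conventional display threshold
#'   for high helicity in the aorta is 200 m/s^2.
#' @return Data frame with columns `time`, `region`, `frac_positive`,
#'   `frac_negative`.
#' @export
threshold_volumes <- function(hel, theta = 200) {
  if (!is.finite(theta) || theta <= 0) stop("theta must be > 0")
  mesh <- hel$mesh
  vol <- mesh$node_volumes
  regions <- c("AAo", "AA", "DAo", "all")
  nt <- ncol(hel$hk)
  out <- expand.grid(time = hel$times, region = regions,
                     stringsAsFactors = FALSE)
  out$frac_positive <- 0; out$frac_negative <- 0
  for (rg in regions) {
    sel <- if (rg == "all") rep(TRUE, length(vol)) else mesh$region_labels == rg
    vr <- vol[sel]; tot <- sum(vr)
    for (m in seq_len(nt)) {
      h <- hel$hk[sel, m]
      row <- out$region == rg & out$time == hel$times[m]
      out$frac_positive[row] <- sum(vr[h >= theta]) / tot
      out$frac_negative[row] <- sum(vr[h <= -theta]) / tot
    }
  }
  out
}

#' Uniform seed points on the inlet disc
#'
#' Approximately `n` points on a uniform Cartesian grid over the inlet
#' cross-section, restricted to `r <= margin * R`.
#'
#' @param mesh A `tube_mesh`.
#' @param n Target number of seeds.
#' @param margin Radial margin as a fraction of the radius (keeps seeds off
#'   the no-slip wall).
#' @param s Axial seeding position (m), default just inside the inlet.
#' @return m x 3 matrix of seed positions.
#' @export
inlet_seed_points <- function(mesh, n = 500L, margin = 0.9, s = 1e-6) {
  R <- mesh$radius * margin
  # grid pitch so that ~n points fall in the disc
  h <- sqrt(pi * R^2 / n)
  g <- seq(-R, R, by = h)
  pts <- expand.grid(x = g, y = g)
  pts <- pts[pts$x^2 + pts$y^2 <= R^2, ]
  cbind(pts$x, pts$y, rep(s, nrow(pts)))
}

# LNH sampled at points/time from a helicity field grid
.sample_lnh <- function(hel, pts, t) {
  nt <- ncol(hel$lnh)
  if (nt == 1L)
    return(as.vector(.interp_nodal(hel$mesh, hel$lnh[, 1], pts)))
  tw <- .time_weights(hel$times, hel$period, t)
  v0 <- .interp_nodal(hel$mesh, hel$lnh[, tw$i0], pts)
  v1 <- .interp_nodal(hel$mesh, hel$lnh[, tw$i1], pts)
  as.vector((1 - tw$a) * v0 + tw$a * v1)
}

#' Lagrangian particle traces through a time-periodic velocity field
#'
#' Advects massless particles with classical fourth-order Runge-Kutta
#' through the velocity field (closed-form evaluator when available,
#' otherwise trilinear spatial and periodic linear temporal interpolation
#' of the nodal samples), sampling local normalized helicity at every
#' accepted step. A particle terminates when it leaves the domain
#' (`exited`) or when the integration reaches `max_cycles` cardiac cycles
#' (`cycle_cap`).
#'
#' @param field A `tv_field`.
#' @param seeds m x 3 matrix of release positions; seeds outside the domain
#'   are skipped with a warning and counted.
#' @param t_release Release time (s).
#' @param dt Integration step (s).
#' @param max_cycles Cycle cap.
#' @param hel Optional precomputed `helicity_field` for LNH sampling;
#'   computed from the field if missing.
#' @param store_positions Keep full trajectories (memory permitting).
#' @return List of `particle_trace` objects with fields `release_time`,
#'   `lnh` (per accepted step), `n_steps`, `termination`, and optionally
#'   `positions`.
#' @export
trace_particles <- function(field, seeds, t_release, dt, max_cycles = 3L,
                            hel = NULL, store_positions = FALSE) {
  if (dt <= 0) stop("dt must be > 0")
  mesh <- field$mesh
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 3)
  if (is.null(hel)) hel <- compute_helicity(field)

  inside <- function(p) {
    r2 <- p[, 1]^2 + p[, 2]^2
    r2 <= (mesh$radius * (1 + 1e-9))^2 &
      p[, 3] >= -1e-12 & p[, 3] <= mesh$length * (1 + 1e-9)
  }
  ok0 <- inside(seeds)
  n_skipped <- sum(!ok0)
  if (n_skipped > 0)
    warning(n_skipped, " seed(s) outside the domain were skipped")
  seeds <- seeds[ok0, , drop = FALSE]
  np <- nrow(seeds)
  if (np == 0L) return(structure(list(), n_skipped = n_skipped))

  n_max <- ceiling(max_cycles * field$period / dt)
  pos <- seeds
  active <- rep(TRUE, np)
  termination <- rep("cycle_cap", np)
  lnh_mat <- matrix(NA_real_, np, n_max + 1L)
  lnh_mat[, 1L] <- .sample_lnh(hel, pos, t_release)
  n_samp <- rep(1L, np)
  pos_arr <- if (store_positions) {
    pa <- array(NA_real_, dim = c(np, 3, n_max + 1L))
    pa[, , 1L] <- seeds
    pa
  } else NULL

  t <- t_release
  for (step in seq_len(n_max)) {
    ia <- which(active)
    if (length(ia) == 0L) break
    p <- pos[ia, , drop = FALSE]
    k1 <- field_eval(field, p, t)
    k2 <- field_eval(field, p + dt / 2 * k1, t + dt / 2)
    k3 <- field_eval(field, p + dt / 2 * k2, t + dt / 2)
    k4 <- field_eval(field, p + dt * k3, t + dt)
    p_new <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
    ok <- inside(p_new)
    keep <- ia[ok]
    if (length(keep) > 0L) {
      pos[keep, ] <- p_new[ok, , drop = FALSE]
      lnh_mat[cbind(keep, step + 1L)] <-
        .sample_lnh(hel, p_new[ok, , drop = FALSE], t)
      n_samp[keep] <- step + 1L
      if (store_positions) pos_arr[keep, , step + 1L] <- p_new[ok, , drop = FALSE]
    }
    gone <- ia[!ok]
    if (length(gone) > 0L) {
      active[gone] <- FALSE
      termination[gone] <- "exited"
    }
  }
  traces <- lapply(seq_len(np), function(i) {
    ns <- n_samp[i]
    structure(list(release_time = t_release, lnh = lnh_mat[i, seq_len(ns)],
                   n_steps = ns,
                   termination = termination[i],
                   positions = if (store_positions)
                     t(pos_arr[i, , seq_len(ns)]) else NULL,
                   dt = dt),
              class = "particle_trace")
  })
  attr(traces, "n_skipped") <- n_skipped
  traces
}

#' Helicity flow index from grouped particle traces
#'
#' For each release time: the mean over surviving particles of the mean
#' `|LNH|` along each trace (the signed variant averages `LNH` without the
#' absolute value). The average HFI is the arithmetic mean over release
#' times. Traces with fewer than `min_steps` accepted steps are excluded.
#'
#' @param traces List of `particle_trace` objects (possibly concatenated
#'   over several release times).
#' @param min_steps Minimum accepted steps for a trace to count.
#' @param signed Use signed LNH instead of `|LNH|`.
#' @return An object of class `hfi_result`: `hfi` named by release time,
#'   `average`, `n_particles` per release.
#' @export
compute_hfi <- function(traces, min_steps = 10L, signed = FALSE) {
  if (length(traces) == 0L) stop("no traces supplied")
  rel <- vapply(traces, function(tr) tr$release_time, numeric(1))
  rel_times <- sort(unique(rel))
  hfi <- numeric(length(rel_times))
  npv <- integer(length(rel_times))
  for (g in seq_along(rel_times)) {
    grp <- traces[rel == rel_times[g]]
    means <- vapply(grp, function(tr) {
      if (tr$n_steps < min_steps) return(NA_real_)
      if (signed) mean(tr$lnh) else mean(abs(tr$lnh))
    }, numeric(1))
    means <- means[is.finite(means)]
    if (length(means) == 0L)
      stop("no surviving traces for release time ", rel_times[g])
    hfi[g] <- mean(means)
    npv[g] <- length(means)
  }
  names(hfi) <- sprintf("T%d", seq_along(rel_times))
  structure(list(hfi = hfi, release_times = rel_times,
                 average = mean(hfi), n_particles = npv, signed = signed),
            class = "hfi_result")
}

#' @export
print.hfi_result <- function(x, ...) {
  cat("HFI by release time:",
      paste(sprintf("%s=%.4f", names(x$hfi), x$hfi), collapse = ", "),
      sprintf("| Avg=%.4f\n", x$average))
  invisible(x)
}

#' Percent differences between HFI results
#'
#' `100 (other - reference) / reference` per release time and for the
#' average. Zero-reference entries are returned as `NA` with a warning
#' rather than silently dropped.
#'
#' @param reference,other `hfi_result` objects on the same release
#'   schedule.
#' @return Named numeric vector (per release time plus `"Avg"`).
#' @export
hfi_percent_diff <- function(reference, other) {
  stopifnot(inherits(reference, "hfi_result"), inherits(other, "hfi_result"))
  if (length(reference$hfi) != length(other$hfi) ||
      max(abs(reference$release_times - other$release_times)) > 1e-12)
    stop("HFI results have different release schedules")
  ref <- c(reference$hfi, Avg = reference$average)
  oth <- c(other$hfi, Avg = other$average)
  out <- ifelse(abs(ref) > 1e-300, 100 * (oth - ref) / ref,
                ifelse(abs(oth) < 1e-12, 0, NA_real_))
  if (any(is.na(out)))
    warning("zero-reference HFI entries flagged as NA")
  names(out) <- names(ref)
  out
}
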