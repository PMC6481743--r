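steady_wss_field <- function(mesh, tau_fun, times = 0, period = 1) {
  # build a wss_field directly from a per-face, per-time traction function
  nf <- nrow(mesh$wall_faces)
  tau <- array(0, dim = c(nf, 3, length(times)))
  for (k in seq_along(times)) tau[, , k] <- tau_fun(times[k])
  structure(list(tau = tau, centroids = mesh$wall_face_centroids,
                 normals = mesh$wall_face_normals,
                 areas = mesh$wall_face_areas,
                 regions = mesh$wall_face_regions,
                 times = times, period = period, mesh = mesh),
            class = "wss_field")
}

test_that("Poiseuille wall shear matches 4 mu Q / (pi R^3) within 5%", {
  mu <- 4e-3; Q <- 1e-4; R <- 0.01
  m <- make_straight_tube_mesh(R, 0.05, 12, 32, 8)
  w <- compute_wss(poiseuille_field(m, Q), fluid_properties())
  mag <- sqrt(rowSums(w$tau[, , 1]^2))
  exact <- 4 * mu * Q / (pi * R^3)
  expect_lt(rel_err(mean(mag), exact), 0.05)
  # shear points upstream (opposes the flow on the wall): tau_z < 0
  expect_true(all(w$tau[, 3, 1] < 0))
  # tangency: tau . n vanishes
  expect_lt(max(abs(rowSums(w$tau[, , 1] * w$normals))),
            1e-8 * max(mag) + 1e-12)
})

test_that("zero and uniform velocity fields produce zero wall shear", {
  m <- fix_mesh()
  z <- aortaBC:::new_tv_field(m, 0,
                              array(0, c(nrow(m$node_positions), 3, 1)))
  expect_equal(max(abs(compute_wss(z)$tau)), 0)
  u <- fix_uniform_field(m, c(0.1, 0.2, 0.3))
  expect_lt(max(abs(compute_wss(u)$tau)), 1e-12)
})

test_that("sign-reversing sinusoidal shear gives OSI 0.5 and TAWSS 2 tau0/pi", {
  m <- fix_mesh(nr = 3, nc = 8, na = 2)
  tau0 <- 2
  nt <- 400
  times <- seq(0, 1, length.out = nt + 1)[seq_len(nt)]
  w <- steady_wss_field(m, function(t) {
    out <- matrix(0, nrow(m$wall_faces), 3)
    out[, 1] <- tau0 * sin(2 * pi * t)
    out
  }, times = times)
  idx <- compute_indices(w)
  expect_lt(max(abs(idx$tawss - 2 * tau0 / pi)), 1e-3 * 2 * tau0 / pi)
  expect_lt(max(abs(idx$osi - 0.5)), 1e-3)
})

test_that("unidirectional shear gives OSI 0 and steady shear keeps its magnitude", {
  m <- fix_mesh(nr = 3, nc = 8, na = 2)
  nt <- 100
  times <- seq(0, 1, length.out = nt + 1)[seq_len(nt)]
  # always positive, time-varying magnitude
  w <- steady_wss_field(m, function(t) {
    out <- matrix(0, nrow(m$wall_faces), 3)
    out[, 1] <- 1 + 0.5 * sin(2 * pi * t)
    out
  }, times = times)
  idx <- compute_indices(w)
  expect_lt(max(idx$osi), 1e-12)
  # single-time steady field: TAWSS equals the instantaneous magnitude
  ws <- steady_wss_field(m, function(t) {
    out <- matrix(0, nrow(m$wall_faces), 3); out[, 2] <- 3; out
  })
  expect_equal(compute_indices(ws)$tawss, rep(3, nrow(m$wall_faces)))
})

test_that("TAWSS is invariant under a time-origin shift", {
  m <- fix_mesh(nr = 3, nc = 8, na = 2)
  nt <- 64
  times <- seq(0, 1, length.out = nt + 1)[seq_len(nt)]
  mk <- function(shift) steady_wss_field(m, function(t) {
    out <- matrix(0, nrow(m$wall_faces), 3)
    out[, 1] <- 1 + 0.8 * sin(2 * pi * (t + shift))
    out[, 3] <- 0.5 * cos(2 * pi * (t + shift))
    out
  }, times = times)
  i0 <- compute_indices(mk(0))
  i1 <- compute_indices(mk(0.3))
  expect_equal(i0$tawss, i1$tawss, tolerance = 1e-10)
  expect_equal(i0$osi, i1$osi, tolerance = 1e-8)
})

test_that("area weighting: summaries, percentile and regional consistency", {
  m <- fix_mesh(nr = 3, nc = 8, na = 6)
  # two-level TAWSS: 1 Pa on half the faces, 3 Pa on the other half
  nf <- nrow(m$wall_faces)
  w <- steady_wss_field(m, function(t) {
    out <- matrix(0, nf, 3)
    out[, 1] <- rep(c(1, 3), each = nf / 2)
    out
  })
  idx <- compute_indices(w)
  expect_equal(idx$mean_tawss, 2, tolerance = 1e-12)
  # upper value at the 99th percentile for a two-level field of equal areas
  expect_equal(idx$p99_tawss, 3, tolerance = 1e-12)
  # whole-surface mean equals the area-weighted combination of regions
  A <- idx$areas
  reg_area <- vapply(c("AAo", "AA", "DAo"),
                     function(rg) sum(A[idx$regions == rg]), numeric(1))
  recomposed <- sum(reg_area * idx$regional_mean_tawss) / sum(reg_area)
  expect_equal(recomposed, idx$mean_tawss, tolerance = 1e-12)

  # two-face weighted quantile worked example
  expect_equal(aortaBC:::weighted_quantile(c(1, 3), c(1, 1), 0.99), 3)
  expect_equal(aortaBC:::weighted_quantile(c(1, 3), c(1, 1), 0.5), 2)
})

test_that("diff maps vanish on self-comparison and scale linearly", {
  m <- fix_mesh(nr = 3, nc = 8, na = 6)
  nf <- nrow(m$wall_faces)
  w <- steady_wss_field(m, function(t) {
    out <- matrix(0, nf, 3)
    out[, 1] <- 1 + m$wall_face_centroids[, 3] * 10
    out
  })
  i1 <- compute_indices(w)
  d0 <- diff_maps(i1, i1)
  expect_equal(max(d0$abs_diff_tawss), 0)
  expect_equal(unname(d0$percent), rep(0, 6))
  # doubled field: +100% everywhere, abs diff equals the reference
  w2 <- w; w2$tau <- 2 * w$tau
  i2 <- compute_indices(w2)
  d2 <- diff_maps(i1, i2)
  expect_equal(unname(d2$percent[c("mean_tawss", "AAo_tawss", "AA_tawss",
                                   "DAo_tawss")]), rep(100, 4),
               tolerance = 1e-10)
  expect_equal(d2$abs_diff_tawss, i1$tawss, tolerance = 1e-12)
  # mismatched meshes are rejected
  m3 <- fix_mesh(nr = 3, nc = 8, na = 4)
  w3 <- steady_wss_field(m3, function(t) matrix(0, nrow(m3$wall_faces), 3))
  expect_error(diff_maps(i1, compute_indices(w3)), "different meshes")
})

test_that("spatiotemporal maps are constant for axisymmetric steady flow", {
  m <- make_straight_tube_mesh(0.01, 0.05, 10, 24, 8)
  w <- compute_wss(poiseuille_field(m, 1e-4))
  stm <- spatiotemporal_map(w, 0.025)
  expect_equal(length(stm$coordinate), 24)
  expect_lt(diff(range(stm$magnitude)), 1e-10 * mean(stm$magnitude))
  # coordinate covers [0, 1) once
  expect_true(all(stm$coordinate >= 0 & stm$coordinate < 1))
  expect_equal(length(unique(stm$coordinate)), 24)
  expect_error(spatiotemporal_map(w, 1.0), "single closed contour")
})

test_that("rotating the wall pattern cyclically shifts the spatiotemporal map", {
  m <- make_straight_tube_mesh(0.01, 0.05, 4, 16, 4)
  nf <- nrow(m$wall_faces)
  base <- function(t) {
    out <- matrix(0, nf, 3)
    th <- atan2(m$wall_face_centroids[, 2], m$wall_face_centroids[, 1])
    out[, 3] <- 2 + cos(th)
    out
  }
  w1 <- steady_wss_field(m, base)
  # same pattern rotated 90 degrees about the tube axis
  w2 <- steady_wss_field(m, function(t) {
    out <- matrix(0, nf, 3)
    th <- atan2(m$wall_face_centroids[, 2], m$wall_face_centroids[, 1])
    out[, 3] <- 2 + cos(th - pi / 2)
    out
  })
  m1 <- spatiotemporal_map(w1, 0.025)$magnitude[, 1]
  m2 <- spatiotemporal_map(w2, 0.025)$magnitude[, 1]
  shift <- 16 / 4
  expect_equal(m2, m1[((seq_len(16) - 1 - shift) %% 16) + 1],
               tolerance = 1e-12)
})

test_that("pulsatile Womersley wall shear is circumferentially uniform and time-varying", {
  m <- make_straight_tube_mesh(0.01, 0.05, 10, 24, 6)
  f <- womersley_field(m, 1e-4, 8e-5, T = 1, n_phases = 20)
  w <- compute_wss(f)
  stm <- spatiotemporal_map(w, 0.025)
  # constant along the circumference at every instant
  circ_var <- apply(stm$magnitude, 2, function(col) diff(range(col)))
  expect_lt(max(circ_var), 1e-8 * max(stm$magnitude))
  # and genuinely varying in time (waveform-shaped)
  expect_gt(diff(range(stm$magnitude[1, ])), 0.2 * max(stm$magnitude))
})
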