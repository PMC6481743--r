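interior_nodes <- function(mesh) {
  r <- sqrt(mesh$node_positions[, 1]^2 + mesh$node_positions[, 2]^2)
  s <- mesh$node_positions[, 3]
  r < mesh$radius - mesh$dr / 2 & s > 1e-12 & s < mesh$length - 1e-12
}

test_that("pure Poiseuille flow has zero helicity density", {
  m <- fix_mesh(nr = 8, nc = 16, na = 6)
  h <- compute_helicity(poiseuille_field(m, 1e-4))
  # velocity is axial, vorticity azimuthal: exactly orthogonal
  expect_lt(max(abs(h$hk)), 1e-10)
  expect_equal(max(abs(h$lnh)), 0)
})

test_that("swirling Poiseuille attains the closed form Hk = 2 Omega W0", {
  m <- make_straight_tube_mesh(0.01, 0.05, 10, 24, 8)
  h <- compute_helicity(swirling_poiseuille_field(m, W0 = 0.5, Omega = 10))
  ii <- interior_nodes(m)
  expect_lt(max(abs(h$hk[ii, 1] / 10 - 1)), 0.05)
  # vorticity axial component is 2 Omega everywhere for solid-body swirl
  expect_lt(max(abs(h$omega[ii, 3, 1] - 20)), 0.2)
})

test_that("mirror reflection flips the sign of helicity density", {
  m <- make_straight_tube_mesh(0.01, 0.05, 8, 16, 6)
  f <- swirling_poiseuille_field(m, W0 = 0.5, Omega = 10)
  # reflect through the x-z plane: y -> -y; the node set is symmetric, and
  # the reflected field at node (x, y, z) is (u, -v, w) of the mirror node
  lc <- aortaBC:::.local_coords(m, m$node_positions)
  mirror <- cbind(m$node_positions[, 1], -m$node_positions[, 2],
                  m$node_positions[, 3])
  vm <- f$evaluator(mirror, 0)
  fm <- aortaBC:::new_tv_field(
    m, 0, array(cbind(vm[, 1], -vm[, 2], vm[, 3]),
                c(nrow(m$node_positions), 3, 1)))
  h <- compute_helicity(f)
  hm <- compute_helicity(fm)
  ii <- interior_nodes(m)
  expect_equal(hm$hk[ii, 1], -h$hk[ii, 1], tolerance = 1e-8)
})

test_that("curl-free fields carry helicity density only at discretization level", {
  # v = grad(phi), phi = x y + 0.5 z x + y z: curl = 0 analytically; the
  # discrete curl inherits the O(dtheta^2) chord-differencing error of the
  # circumferential stencil, so Hk must be small relative to |v| |grad v|
  # and shrink under circumferential refinement
  ev <- function(p, t) cbind(p[, 2] + 0.5 * p[, 3],
                             p[, 1] + p[, 3],
                             0.5 * p[, 1] + p[, 2])
  hk_err <- function(nc) {
    m <- make_straight_tube_mesh(0.01, 0.05, 10, nc, 8)
    f <- aortaBC:::new_tv_field(m, 0, aortaBC:::.sample_evaluator(m, 0, ev),
                                evaluator = ev)
    h <- compute_helicity(f)
    vscale <- max(sqrt(rowSums(f$velocity[, , 1]^2)))
    gscale <- 2.2    # norm of the (constant) velocity-gradient tensor
    max(abs(h$hk)) / (vscale * gscale)
  }
  e1 <- hk_err(24)
  expect_lt(e1, 0.02)
  # second-order decay in the circumferential spacing
  expect_lt(hk_err(48), 0.35 * e1)
})

test_that("LNH is bounded and zero where velocity or vorticity vanish", {
  m <- make_straight_tube_mesh(0.015, 0.15, 8, 16, 8)
  wf <- fix_waveform()
  f <- valve_jet_field(m, wf, swirl_strength = 0.25, seed = 4L, n_phases = 8)
  h <- compute_helicity(f)
  expect_true(all(h$lnh >= -1 & h$lnh <= 1))
  z <- aortaBC:::new_tv_field(m, 0, array(0, c(nrow(m$node_positions), 3, 1)))
  expect_equal(max(abs(compute_helicity(z)$lnh)), 0)
})

test_that("threshold volumes follow hand-built helicity distributions", {
  m <- fix_mesh(nr = 6, nc = 12, na = 6)
  f <- poiseuille_field(m, 1e-4)
  h <- compute_helicity(f)
  # uniform Hk = 10 below theta = 200: zero fractions
  h$hk[] <- 10
  tv <- threshold_volumes(h, theta = 200)
  expect_true(all(tv$frac_positive == 0) && all(tv$frac_negative == 0))
  # uniform Hk = 250: whole volume positive
  h$hk[] <- 250
  tv <- threshold_volumes(h, theta = 200)
  expect_true(all(tv$frac_positive == 1) && all(tv$frac_negative == 0))
  # half-domain +300 / -300 split by volume
  vol <- m$node_volumes
  o <- order(m$node_positions[, 3])
  half <- o[cumsum(vol[o]) <= sum(vol) / 2]
  h$hk[] <- 300
  h$hk[half, ] <- -300
  tv <- threshold_volumes(h, theta = 200)
  whole <- tv[tv$region == "all", ]
  expect_equal(whole$frac_positive, 1 - sum(vol[half]) / sum(vol),
               tolerance = 1e-9)
  expect_equal(whole$frac_negative, sum(vol[half]) / sum(vol),
               tolerance = 1e-9)
  expect_error(threshold_volumes(h, theta = 0), "theta")
})

test_that("uniform fields advect particles along exact straight lines", {
  m <- make_straight_tube_mesh(0.01, 1.0, 4, 8, 2)
  f <- fix_uniform_field(m, c(0, 0, 0.3))
  hel <- compute_helicity(f)
  tr <- trace_particles(f, matrix(c(0.002, 0.003, 0), 1), 0, 0.01,
                        max_cycles = 3, hel = hel, store_positions = TRUE)
  pos <- tr[[1]]$positions
  expect_lt(max(abs(pos[, 1] - 0.002)), 1e-12)
  expect_lt(max(abs(pos[, 2] - 0.003)), 1e-12)
  # z advances linearly at 0.3 m/s
  expect_equal(pos[nrow(pos), 3] - pos[1, 3],
               0.3 * 0.01 * (nrow(pos) - 1), tolerance = 1e-12)
})

test_that("the tracer shows fourth-order self-convergence on a smooth swirl", {
  m <- make_straight_tube_mesh(0.01, 1.0, 4, 8, 2)
  f <- swirling_poiseuille_field(m, W0 = 0.05, Omega = 10)
  hel <- compute_helicity(f)
  fin <- function(dt) {
    tr <- trace_particles(f, matrix(c(0.005, 0, 0.001), 1), 0, dt,
                          max_cycles = 2, hel = hel, store_positions = TRUE)
    tr[[1]]$positions[tr[[1]]$n_steps, ]
  }
  p1 <- fin(0.02); p2 <- fin(0.01); p3 <- fin(0.005)
  e1 <- sqrt(sum((p1 - p2)^2)); e2 <- sqrt(sum((p2 - p3)^2))
  expect_gt(log2(e1 / e2), 3.8)
  # orbit stays at its release radius (solid-body rotation in-plane)
  tr <- trace_particles(f, matrix(c(0.005, 0, 0.001), 1), 0, 0.005,
                        max_cycles = 2, hel = hel, store_positions = TRUE)
  r <- sqrt(rowSums(tr[[1]]$positions[, 1:2]^2))
  expect_lt(max(abs(r - 0.005)), 1e-7)
})

test_that("seeds outside the domain are skipped with a warning", {
  m <- make_straight_tube_mesh(0.01, 1.0, 4, 8, 2)
  f <- fix_uniform_field(m, c(0, 0, 0.3))
  hel <- compute_helicity(f)
  expect_warning(
    tr <- trace_particles(f, rbind(c(0, 0, 0.1), c(0.02, 0, 0.1)), 0, 0.01,
                          hel = hel),
    "skipped")
  expect_length(tr, 1L)
  expect_equal(attr(tr, "n_skipped"), 1L)
})

test_that("steady Poiseuille traces carry identically zero LNH", {
  m <- make_straight_tube_mesh(0.01, 0.2, 8, 16, 6)
  f <- poiseuille_field(m, 1e-4)
  hel <- compute_helicity(f)
  seeds <- inlet_seed_points(m, n = 20, s = 0.01)
  tr <- trace_particles(f, seeds, 0, 0.005, max_cycles = 2, hel = hel)
  for (t in tr) expect_lt(max(abs(t$lnh)), 1e-9)
})

test_that("HFI reduces correctly for degenerate LNH profiles", {
  mk_trace <- function(lnh, release) structure(
    list(release_time = release, lnh = lnh, n_steps = length(lnh),
         termination = "exited", positions = NULL, dt = 1e-3),
    class = "particle_trace")
  # all-zero LNH -> HFI 0
  tr0 <- lapply(1:3, function(i) mk_trace(rep(0, 20), 0.1))
  expect_equal(compute_hfi(tr0)$average, 0)
  # constant LNH = -0.8 -> HFI 0.8 (absolute value), -0.8 signed
  trc <- lapply(1:3, function(i) mk_trace(rep(-0.8, 20), 0.1))
  expect_equal(compute_hfi(trc)$average, 0.8)
  expect_equal(compute_hfi(trc, signed = TRUE)$average, -0.8)
  # short traces are excluded; all-short groups error
  mix <- c(trc, list(mk_trace(rep(1, 3), 0.1)))
  expect_equal(compute_hfi(mix)$n_particles, 3L)
  expect_error(compute_hfi(list(mk_trace(rep(1, 3), 0.1))), "no surviving")
  # four release times average arithmetically
  tr4 <- unlist(lapply(1:4, function(g)
    lapply(1:2, function(i) mk_trace(rep(0.1 * g, 20), g / 10))),
    recursive = FALSE)
  res <- compute_hfi(tr4)
  expect_equal(unname(res$hfi), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(res$average, 0.25)
})

test_that("HFI on the swirl oracle matches an independent dense integration", {
  m <- make_straight_tube_mesh(0.01, 0.3, 10, 24, 10)
  W0 <- 0.25; Om <- 15
  f <- swirling_poiseuille_field(m, W0 = W0, Omega = Om)
  hel <- compute_helicity(f)
  seeds <- rbind(c(0.002, 0, 0.001), c(0.005, 0.001, 0.001),
                 c(-0.004, 0.004, 0.001), c(0, -0.0065, 0.001))
  tr <- trace_particles(f, seeds, 0, dt = 0.005, max_cycles = 3, hel = hel)
  impl <- compute_hfi(tr, min_steps = 5)$average

  # independent oracle: dense RK4 with tiny dt on the closed-form field,
  # analytic LNH along the trace
  lnh_exact <- function(p) {
    r2 <- p[1]^2 + p[2]^2
    v <- c(-Om * p[2], Om * p[1], W0 * (1 - r2 / 0.01^2))
    om <- c(-2 * W0 * p[2] / 0.01^2, 2 * W0 * p[1] / 0.01^2, 2 * Om)
    sum(v * om) / (sqrt(sum(v^2)) * sqrt(sum(om^2)))
  }
  vel <- function(p) c(-Om * p[2], Om * p[1],
                       W0 * max(1 - (p[1]^2 + p[2]^2) / 0.01^2, 0))
  oracle_means <- vapply(seq_len(nrow(seeds)), function(i) {
    p <- seeds[i, ]; dt <- 5e-4
    lnhs <- lnh_exact(p)
    for (k in seq_len(ceiling(3 * 1 / dt))) {
      k1 <- vel(p); k2 <- vel(p + dt / 2 * k1); k3 <- vel(p + dt / 2 * k2)
      k4 <- vel(p + dt * k3)
      p <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (p[3] > 0.3 || p[3] < 0) break
      lnhs <- c(lnhs, lnh_exact(p))
    }
    mean(abs(lnhs))
  }, numeric(1))
  expect_lt(rel_err(impl, mean(oracle_means)), 0.01)
})

test_that("HFI percent differences are signed and guard zero references", {
  mk <- function(vals) structure(
    list(hfi = stats::setNames(vals, sprintf("T%d", seq_along(vals))),
         release_times = seq_along(vals) / 10, average = mean(vals),
         n_particles = rep(5L, length(vals)), signed = FALSE),
    class = "hfi_result")
  a <- mk(c(0.2, 0.4, 0.3, 0.1))
  expect_equal(unname(hfi_percent_diff(a, a)), rep(0, 5))
  b <- mk(1.5 * c(0.2, 0.4, 0.3, 0.1))
  expect_equal(unname(hfi_percent_diff(a, b)), rep(50, 5), tolerance = 1e-12)
  z <- mk(c(0, 0.4, 0.3, 0.1))
  expect_warning(d <- hfi_percent_diff(z, a), "zero-reference")
  expect_true(is.na(d[["T1"]]))
  expect_false(anyNA(d[c("T2", "T3", "T4")]))
})
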