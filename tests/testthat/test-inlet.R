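test_that("coincident reference points give the identity transform", {
  P <- fix_ref_points()
  tr <- fit_plane_to_inlet_transform(P, P)
  expect_lt(max(abs(tr$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(tr$translation)), 1e-12)
  expect_lt(tr$rms_fit_error, 1e-12)
})

test_that("known rigid transforms are recovered from 4 correspondences", {
  P <- fix_ref_points()
  angles <- c(30, 110, 250) * pi / 180
  for (th in angles) {
    Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    tv <- c(0.1, -0.2, 0.05)
    Q <- P %*% t(Rz) + matrix(tv, 4, 3, byrow = TRUE)
    tr <- fit_plane_to_inlet_transform(P, Q)
    expect_lt(max(abs(tr$rotation - Rz)), 1e-10)
    expect_lt(max(abs(tr$translation - tv)), 1e-12)
    expect_equal(det(tr$rotation), 1, tolerance = 1e-12)
    # orthonormality
    expect_lt(max(abs(crossprod(tr$rotation) - diag(3))), 1e-10)
    # round trip through apply_transform
    expect_lt(max(abs(apply_transform(tr, P) - Q)), 1e-12)
    expect_lt(max(abs(apply_transform(tr, Q, inverse = TRUE) - P)), 1e-12)
  }
})

test_that("similarity fit recovers a uniform scale when allowed", {
  P <- fix_ref_points()
  Q <- 1.7 * P
  tr <- fit_plane_to_inlet_transform(P, Q, allow_scale = TRUE)
  expect_equal(tr$scale, 1.7, tolerance = 1e-12)
  expect_lt(tr$rms_fit_error, 1e-12)
})

test_that("degenerate correspondence sets are rejected", {
  P <- fix_ref_points()
  expect_error(fit_plane_to_inlet_transform(P[1:3, ], P[1:3, ]), ">= 4")
  coll <- cbind(seq(0, 1, length.out = 4), 0, 0)
  expect_error(fit_plane_to_inlet_transform(coll, coll), "collinear")
})

test_that("FLAT profile is Q(t)/A along the patch normal", {
  m <- fix_mesh()
  wf <- fix_waveform()
  f <- plug_field(m, wf, n_phases = 10)
  mp <- acquire_plane(f, plane_spec(), slab_thickness_mm = 0, noise_sd = 0)
  tr <- identity_transform(m$radius)
  tt <- c(0, 0.2, 0.5)
  bc <- build_inlet_bc(mp, tr, m, "flat", tt, wf)
  for (k in seq_along(tt)) {
    expected <- wf$Q_fun(tt[k]) / m$inlet_area
    expect_lt(max(abs(bc$velocity[, 3, k] - expected)), 1e-12 * expected)
    expect_true(all(bc$velocity[, 1:2, k] == 0))
  }
})

test_that("a uniform purely-normal map makes all three variants identical", {
  m <- fix_mesh()
  wf <- fix_waveform()
  f <- plug_field(m, wf, n_phases = 10)
  mp <- acquire_plane(f, plane_spec(), slab_thickness_mm = 1, noise_sd = 0)
  tr <- identity_transform(m$radius)
  tt <- seq(0, 0.9, by = 0.1)
  b3 <- build_inlet_bc(mp, tr, m, "3d", tt, wf)
  btp <- build_inlet_bc(mp, tr, m, "tp", tt, wf)
  bfl <- build_inlet_bc(mp, tr, m, "flat", tt, wf)
  expect_lt(max(abs(b3$velocity - bfl$velocity)), 1e-12)
  expect_lt(max(abs(btp$velocity - bfl$velocity)), 1e-12)
})

test_that("all variants conserve the waveform flux; TP is the normal projection of 3D", {
  m <- make_straight_tube_mesh(0.015, 0.15, 8, 16, 8)
  wf <- fix_waveform()
  f <- valve_jet_field(m, wf, swirl_strength = 0.2, seed = 3L, n_phases = 30)
  mp <- acquire_plane(f, plane_spec(), slab_thickness_mm = 1, noise_sd = 0)
  tr <- identity_transform(m$radius)
  tt <- f$times
  Q_target <- vapply(tt, wf$Q_fun, numeric(1))
  for (v in c("3d", "tp", "flat")) {
    bc <- build_inlet_bc(mp, tr, m, v, tt, wf)
    expect_lt(max(abs(bc$flux / Q_target - 1)), 1e-6)
    if (v != "3d") expect_true(all(bc$velocity[, 1:2, ] == 0))
  }
  # TP velocities are the normal projection of the 3D ones up to the
  # per-variant flux rescaling (identical here since in-plane components
  # carry no flux)
  b3 <- build_inlet_bc(mp, tr, m, "3d", tt, wf)
  btp <- build_inlet_bc(mp, tr, m, "tp", tt, wf)
  expect_equal(btp$velocity[, 3, ], b3$velocity[, 3, ], tolerance = 1e-10)

  expect_error(build_inlet_bc(mp, tr, m, "3d", c(0, 1.5), wf), "within")
})

test_that("decomposition statistics match hand-computable maps", {
  m <- fix_mesh(length = 0.1, na = 4)
  # 3-4-5 uniform map
  f <- fix_uniform_field(m, c(0.3, 0, 0.4))
  mp <- acquire_plane(f, plane_spec(origin = c(0, 0, 0.05)),
                      slab_thickness_mm = 0, noise_sd = 0, venc = 2)
  ds <- decomposition_stats(mp)
  expect_equal(ds$summary$v_mean_total, 0.5, tolerance = 1e-12)
  expect_equal(ds$summary$v_mean_normal, 0.4, tolerance = 1e-12)
  expect_equal(ds$summary$inplane_fraction, 60, tolerance = 1e-9)
  expect_equal(ds$summary$inplane_fraction,
               mean(ds$per_phase$inplane_fraction_pixelwise), tolerance = 1e-9)

  # purely axial Poiseuille: no in-plane content, normal = total
  fp <- poiseuille_field(m, 1e-4)
  mpp <- acquire_plane(fp, plane_spec(origin = c(0, 0, 0.05)),
                       slab_thickness_mm = 0, noise_sd = 0, venc = 2)
  dsp <- decomposition_stats(mpp)
  expect_equal(dsp$summary$inplane_fraction, 0)
  expect_equal(dsp$summary$v_mean_normal, dsp$summary$v_mean_total)
})

test_that("in-plane fraction is invariant under rotation of the in-plane axes", {
  m <- make_straight_tube_mesh(0.015, 0.15, 8, 16, 8)
  wf <- fix_waveform()
  f <- valve_jet_field(m, wf, swirl_strength = 0.2, seed = 3L, n_phases = 8)
  mp <- acquire_plane(f, plane_spec(), slab_thickness_mm = 0, noise_sd = 0,
                      venc = 3)
  # re-express the same map in rotated in-plane axes: |v_inplane| per pixel
  # is unchanged, so every decomposition statistic must be too
  th <- 37 * pi / 180
  mp2 <- mp
  mp2$vel_u <- cos(th) * mp$vel_u + sin(th) * mp$vel_v
  mp2$vel_v <- -sin(th) * mp$vel_u + cos(th) * mp$vel_v
  mp2$plane$axis_u <- cos(th) * mp$plane$axis_u + sin(th) * mp$plane$axis_v
  mp2$plane$axis_v <- -sin(th) * mp$plane$axis_u + cos(th) * mp$plane$axis_v
  d1 <- decomposition_stats(mp)
  d2 <- decomposition_stats(mp2)
  expect_equal(d1$per_phase$inplane_fraction, d2$per_phase$inplane_fraction,
               tolerance = 1e-12)
  expect_equal(d1$summary$v_mean_total, d2$summary$v_mean_total,
               tolerance = 1e-12)
})

test_that("mean/max pointwise bound propagates to the summary statistics", {
  m <- make_straight_tube_mesh(0.015, 0.15, 8, 16, 8)
  wf <- fix_waveform()
  f <- valve_jet_field(m, wf, swirl_strength = 0.25, seed = 5L, n_phases = 12)
  mp <- acquire_plane(f, plane_spec(), noise_sd = 0)
  ds <- decomposition_stats(mp)
  expect_true(all(ds$per_phase$mean_normal <= ds$per_phase$mean_total + 1e-15))
  expect_true(all(ds$per_phase$max_normal <= ds$per_phase$max_total + 1e-15))
  expect_true(all(ds$per_phase$inplane_fraction >= 0 &
                    ds$per_phase$inplane_fraction <= 100))
})

test_that("underestimation percentages reproduce the worked examples", {
  # stenotic-valve worked example: mean 0.16 vs 0.27 m/s -> 41%
  expect_equal(as.integer(underestimation_percent(0.16, 0.27)), 41L)
  # mechanical-valve worked example: mean 0.14 vs 0.21 m/s -> 33%
  expect_equal(as.integer(underestimation_percent(0.14, 0.21)), 33L)
  expect_equal(as.integer(underestimation_percent(0.5, 0.5)), 0L)
  expect_equal(attr(underestimation_percent(0.66, 0.82), "exact"),
               100 * (1 - 0.66 / 0.82))
  expect_error(underestimation_percent(0.3, 0.2), "cannot exceed")
  expect_error(underestimation_percent(0.3, 0), "must be > 0")
})
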