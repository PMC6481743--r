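# Shared fixtures: small meshes, waveforms and fields built in code.

fix_mesh <- function(radius = 0.01, length = 0.05, nr = 8, nc = 16, na = 6,
                     ...) {
  make_straight_tube_mesh(radius, length, nr, nc, na, ...)
}

fix_waveform <- function(n = 50) cardiac_waveform(n_samples = n)

# four non-collinear reference points on a circle of radius R at z = 0
fix_ref_points <- function(R = 0.01) {
  rbind(c(R, 0, 0), c(0, R, 0), c(-R, 0, 0), c(0, -R, 0))
}

identity_transform <- function(R = 0.01) {
  P <- fix_ref_points(R)
  fit_plane_to_inlet_transform(P, P)
}

# uniform constant-velocity field with closed-form evaluator
fix_uniform_field <- function(mesh, v = c(0.3, 0, 0.4)) {
  ev <- function(p, t) matrix(v, nrow(p), 3, byrow = TRUE)
  aortaBC:::new_tv_field(
    mesh, times = 0,
    velocity = aortaBC:::.sample_evaluator(mesh, 0, ev),
    evaluator = ev, kind = "uniform")
}

rel_err <- function(x, ref) abs(x / ref - 1)

# relative L2 over an [n, 3, nt] pair
rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))
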