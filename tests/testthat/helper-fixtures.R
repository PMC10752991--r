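# Shared fixtures and independent oracles used across the test files.

# Tuned (stiff) tendon parameter set; the calibrated values used throughout.
tuned_see <- function(l_see_0 = NA_real_) see_params(0.8, 0.02, 0.01, l_see_0)

# Single-digit pin-wrap fixture: a two-point path straddling one joint with
# both via points at palmar offset r. Used for the moment-arm oracles.
pin_wrap_fixture <- function(r = 0.005, d = 0.012, digit_id = 3) {
  dig <- digit_geometry(digit_id, c(0.045, 0.026, 0.017))
  path <- routing_path("FDP 3", data.frame(
    segment = c(0, 1), x = c(-d, d), y = c(-r, -r)), digit_id)
  list(digit = dig, path = path, r = r, d = d)
}

# Analytic moment arm of a straight chord between a parent-frame point A and
# a child-frame point B about the joint at the origin: the perpendicular
# distance from the joint center to the chord (the discrete-pulley tangency
# distance), signed by the flexion convention.
chord_arm_oracle <- function(A_local, B_local, q) {
  A <- A_local
  B <- c(cos(-q) * B_local[1] - sin(-q) * B_local[2],
         sin(-q) * B_local[1] + cos(-q) * B_local[2])
  # r = -dL/dq reduces to cross(A, B) / |B - A| for a rigid chord endpoint
  # rotating with the child segment (flexion-positive convention)
  (A[1] * B[2] - A[2] * B[1]) / sqrt(sum((B - A)^2))
}

# Virtual-work / force-equilibrium oracle for the moment arm of a routed
# path: apply unit tension along the polyline, sum the via-point nodal
# forces, and take moments about the joint center for all points distal to
# the joint. Independent of the tendon-excursion derivative route.
torque_from_tension_oracle <- function(digit, path, q, joint_idx, F = 1) {
  vp <- path$via_points
  P <- t(vapply(seq_len(nrow(vp)), function(i) {
    jfisim:::point_world(digit, q, vp$segment[i], c(vp$x[i], vp$y[i]))
  }, numeric(2)))
  n <- nrow(P)
  u <- diff(P)
  u <- u / sqrt(rowSums(u^2))
  fk <- jfisim:::fk_digit(digit, q)
  cj <- fk$origins[joint_idx + 1, ]
  tau <- 0
  for (i in seq_len(n)) {
    f <- c(0, 0)
    if (i > 1) f <- f - F * u[i - 1, ]      # pull toward previous point
    if (i < n) f <- f + F * u[i, ]          # pull toward next point
    if (vp$segment[i] >= joint_idx) {
      rvec <- P[i, ] - cj
      # planar moment, converted to the flexion-positive convention
      tau <- tau - (rvec[1] * f[2] - rvec[2] * f[1])
    }
  }
  tau
}

# Simpson integration of the moment arm over a flexion ramp of one joint.
integrate_arm <- function(digit, path, joint_idx, q_from, q_to, n = 201) {
  stopifnot(n %% 2 == 1)
  qs <- seq(q_from, q_to, length.out = n)
  vals <- vapply(qs, function(ang) {
    q <- c(0, 0, 0); q[joint_idx] <- ang
    moment_arm(digit, path, q, joint_idx)
  }, numeric(1))
  h <- (q_to - q_from) / (n - 1)
  w <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1)
  h / 3 * sum(w * vals)
}

# Brute-force contraction-rate oracle: coarse grid scan of the force-balance
# residual followed by derivative-free bisection on the sign change.
brute_force_vce <- function(params, state, v_mtu, vcap = NULL) {
  if (is.null(vcap)) vcap <- 20 * params$ce$l_ce_opt
  f <- function(v) jfisim:::mtu_force_residual(params, state, v_mtu, v)
  grid <- seq(-vcap, vcap, length.out = 4001)
  rv <- vapply(grid, f, numeric(1))
  k <- which(rv[-1] * rv[-length(rv)] <= 0)[1]
  if (is.na(k)) return(grid[which.min(abs(rv))])
  lo <- grid[k]; hi <- grid[k + 1]
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Small single-digit hand model (no rod) for chain-dynamics tests.
single_digit_model <- function() {
  dig <- digit_geometry(3, c(0.045, 0.026, 0.017))
  joints <- list(revolute_joint(), revolute_joint(rom = c(0, 100 * pi / 180)),
                 revolute_joint(rom = c(0, 80 * pi / 180)))
  path <- routing_path("FDP 3", data.frame(
    segment = c(0, 0, 1, 1, 2, 2, 3, 3),
    x = c(-0.2, -0.012, 0.012, 0.035, 0.010, 0.018, 0.008, 0.010),
    y = c(-0.005, -0.0097, -0.0097, -0.0075, -0.0075, -0.005, -0.005,
          -0.002)), 3)
  l_mtu <- path_length(dig, path, c(0, 0, 0))
  eq <- init_equilibrium(l_mtu, 0.09, "flexor", name = "FDP 3")
  mtu <- mtu_params("FDP 3", Fmax = 100, csa = 100 / 30e6,
                    see = see_params(0.8, 0.02, 0.01, eq$l_see_0),
                    ce = ce_params(0.09), group = "flexor")
  hand_model(list(dig), joints, list(path), list(mtu))
}
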