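# Planar digit kinematics, tendon-excursion moment arms and chain dynamics.

test_that("path length is the polyline length through via points", {
  dig <- digit_geometry(3, c(0.045, 0.026, 0.017))
  p_same <- routing_path("FDP 3", data.frame(
    segment = c(1, 1), x = c(0.00, 0.10), y = c(-0.003, -0.003)), 3)
  for (q1 in c(0, 0.5, 1.2)) {
    expect_equal(path_length(dig, p_same, c(q1, 0.3, 0.1)), 0.10)
  }
  p_span <- routing_path("FDP 3", data.frame(
    segment = c(0, 0, 1), x = c(-0.06, -0.03, 0.03), y = c(-0.002, -0.002,
                                                           -0.002)), 3)
  expect_equal(path_length(dig, p_span, c(0, 0, 0)), 0.09)
  p_bad <- routing_path("FDP 3", data.frame(
    segment = c(1, 1), x = c(0.01, 0.01), y = c(-0.003, -0.003)), 3)
  expect_error(path_length(dig, p_bad, c(0, 0, 0)), "coincident")
})

test_that("a symmetric wrap pair lengthens the path by ~r * dq under flexion", {
  fx <- pin_wrap_fixture(r = 0.005)
  dq <- 1e-3
  L0 <- path_length(fx$digit, fx$path, c(0, 0, 0))
  L1 <- path_length(fx$digit, fx$path, c(-dq, 0, 0))  # extension lengthens
  expect_equal((L1 - L0) / dq, fx$r, tolerance = 1e-3)
})

test_that("central-difference moment arm matches the analytic chord oracle", {
  for (r in c(0.003, 0.005, 0.009)) {
    fx <- pin_wrap_fixture(r = r)
    for (q1 in seq(0, pi / 2, length.out = 19)) {
      arm <- moment_arm(fx$digit, fx$path, c(q1, 0, 0), 1)
      oracle <- chord_arm_oracle(c(-fx$d, -r), c(fx$d, -r), q1)
      expect_lt(abs(arm - oracle), 1e-6)
    }
    # at the straight posture the arm equals the wrap radius exactly
    expect_equal(moment_arm(fx$digit, fx$path, c(0, 0, 0), 1), r,
                 tolerance = 1e-9)
  }
})

test_that("mirroring a path to the dorsal side flips the moment arm sign", {
  fx <- pin_wrap_fixture(r = 0.005)
  mirrored <- routing_path("EXT 3", data.frame(
    segment = c(0, 1), x = c(-fx$d, fx$d), y = c(0.005, 0.005)), 3)
  expect_equal(moment_arm(fx$digit, mirrored, c(0, 0, 0), 1),
               -moment_arm(fx$digit, fx$path, c(0, 0, 0), 1),
               tolerance = 1e-12)
  # flexion of the dorsal path mirrors extension of the palmar path
  expect_equal(moment_arm(fx$digit, mirrored, c(0.4, 0, 0), 1),
               -moment_arm(fx$digit, fx$path, c(-0.4, 0, 0), 1),
               tolerance = 1e-9)
})

test_that("a path not crossing the joint yields a zero arm with a warning", {
  dig <- digit_geometry(3, c(0.045, 0.026, 0.017))
  p <- routing_path("FDS 3", data.frame(
    segment = c(0, 1), x = c(-0.01, 0.01), y = c(-0.005, -0.005)), 3)
  expect_warning(a <- moment_arm(dig, p, c(0, 0, 0), 3), "does not cross")
  expect_equal(a, 0)
})

test_that("moment arms satisfy the virtual-work (force equilibrium) oracle", {
  m <- single_digit_model()
  dig <- m$digits[[1]]; p <- m$paths[[1]]
  for (q in list(c(0.2, 0.5, 0.3), c(0.8, 1.0, 0.6), c(0.05, 0.1, 0.02))) {
    for (j in 1:3) {
      arm <- moment_arm(dig, p, q, j)
      tau <- torque_from_tension_oracle(dig, p, q, j, F = 1)
      expect_equal(arm, tau, tolerance = 1e-6)
    }
  }
})

test_that("integrated moment arm equals the path length change", {
  m <- single_digit_model()
  dig <- m$digits[[1]]; p <- m$paths[[1]]
  for (j in 1:3) {
    q_to <- c(1.2, 1.4, 1.0)[j]
    excursion <- integrate_arm(dig, p, j, 0, q_to)
    q1 <- c(0, 0, 0); q1[j] <- q_to
    dL <- path_length(dig, p, c(0, 0, 0)) - path_length(dig, p, q1)
    # flexors shorten the path under flexion: excursion = -delta L
    expect_equal(excursion, dL, tolerance = 1e-8)
    expect_gt(excursion, 0)
  }
})

test_that("the exact path gradients agree with central differences", {
  model <- gen_hand_fixture()
  sc <- model$scene
  set.seed(3)
  q <- matrix(runif(12, 0, 1), 4, 3)
  sev <- jfisim:::scene_eval(sc, q)
  h <- 1e-6
  for (k in seq_along(model$paths)) {
    p <- model$paths[[k]]
    d <- model$digits[[paste0("d", p$digit_id)]]
    di <- match(paste0("d", p$digit_id), names(model$digits))
    for (j in 1:3) {
      qp <- q[di, ]; qp[j] <- qp[j] + h
      qm <- q[di, ]; qm[j] <- qm[j] - h
      num <- (path_length(d, p, qp) - path_length(d, p, qm)) / (2 * h)
      expect_equal(sev$dL[k, j], num, tolerance = 1e-5)
    }
  }
})

test_that("full flexor topology yields exactly 20 moment-arm curves", {
  model <- gen_hand_fixture()
  curves <- model_moment_arm_curves(model)
  expect_length(curves, 20)
  tab <- table(vapply(curves, `[[`, "", "muscle"))
  expect_equal(unname(tab[["FDP"]]), 12)   # 3 joints x 4 digits
  expect_equal(unname(tab[["FDS"]]), 8)    # 2 joints x 4 digits
})

test_that("joint torques combine muscle moments, passive terms and limits", {
  m <- single_digit_model()
  q0 <- c(0, 0, 0)
  tau0 <- joint_torques(m, q0, c("FDP 3" = 0))
  expect_equal(unname(tau0[1, ]), c(0, 0, 0))
  # single strand with force F contributes exactly r * F
  F <- 50
  tauF <- joint_torques(m, q0, c("FDP 3" = F))
  for (j in 1:3) {
    r <- moment_arm(m$digits[[1]], m$paths[[1]], q0, j)
    expect_equal(unname(tauF[1, j]), r * F, tolerance = 1e-10)
  }
  # beyond the ROM limit the penalty torque restores into range
  q_over <- c(pi / 2 + 0.1, 0, 0)
  tau_over <- joint_torques(m, q_over, c("FDP 3" = 0))
  expect_lt(tau_over[1, 1], -1)   # strong extension torque
})

test_that("chain dynamics hold equilibria and converge with dt", {
  m <- single_digit_model()
  s0 <- hand_state(c(0, 0, 0))
  s1 <- step_dynamics(m, s0, matrix(0, 1, 3), 2e-5)
  expect_equal(s1$q, s0$q, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(s1$qdot, s0$qdot, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(step_dynamics(m, s0, matrix(0, 1, 3), 1e-3), "dt_max")

  # constant flexion torque: monotone flexion until the ROM penalty balances
  run <- function(dt, t_end, tau) {
    s <- hand_state(c(0, 0, 0))
    qs <- numeric(0)
    for (i in seq_len(round(t_end / dt))) {
      s <- step_dynamics(m, s, tau, dt)
      if (i %% 100 == 0) qs <- c(qs, s$q[1, 1])
    }
    list(s = s, qs = qs)
  }
  tau <- matrix(c(0.02, 0, 0), 1, 3)
  out <- run(2e-5, 0.1, tau)
  expect_true(all(diff(out$qs[1:20]) > -1e-9))
  expect_lt(out$s$q[1, 1], pi / 2 + 0.05)   # held near the limit
  # halving dt changes the outcome by less than 1e-4 rad
  out2 <- run(1e-5, 0.1, tau)
  expect_lt(max(abs(out2$s$q - out$s$q)), 1e-4)

  # passive unforced motion with damping stays bounded over 0.2 s
  s <- hand_state(c(0.3, 0.4, 0.2), c(2, -1, 1))
  for (i in 1:10000) s <- step_dynamics(m, s, matrix(0, 1, 3), 2e-5)
  expect_true(all(abs(s$q) < 3) && all(abs(s$qdot) < 50))
})
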