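# Muscle-tendon-unit mechanics: tendon force law, modulus, force-length,
# activation dynamics, initialization and contraction dynamics.

test_that("tendon force law reproduces the piecewise branches", {
  see <- tuned_see(l_see_0 = 0.1)
  expect_equal(see_force(see, 100, 0.1 * 0.95), 0)          # slack
  expect_equal(see_force(see, 100, 0.1 * 1.02), 80)         # transition
  expect_equal(see_force(see, 100, 0.1 * 1.01), 20)         # toe, nu = 2
  expect_equal(see_force(see, 100, 0.1 * 1.03), 160)        # linear
  expect_error(see_force(see, 100, -0.01), "non-negative")
  expect_error(see_force(see, 100, NaN), "non-finite")
})

test_that("tendon force is C0 and C1 at the toe/linear transition", {
  set.seed(11)
  for (i in 1:100) {
    dl <- runif(1, 0.004, 0.03)
    nll <- dl * runif(1, 1.2, 4)
    see <- see_params(runif(1, 0.2, 1.2), nll, dl, l_see_0 = 0.2)
    Fmax <- runif(1, 50, 2000)
    h <- 1e-9
    l_at <- 0.2 * (1 + nll)
    f_lo <- see_force(see, Fmax, l_at - 0.2 * h)
    f_hi <- see_force(see, Fmax, l_at + 0.2 * h)
    expect_lt(abs(f_hi - f_lo), 1e-4 * Fmax)                # C0
    slope_lo <- (see_force(see, Fmax, l_at) -
                 see_force(see, Fmax, l_at - 0.2 * 1e-7)) / (0.2 * 1e-7)
    slope_hi <- (see_force(see, Fmax, l_at + 0.2 * 1e-7) -
                 see_force(see, Fmax, l_at)) / (0.2 * 1e-7)
    expect_lt(abs(slope_hi / slope_lo - 1), 1e-4)           # C1
    # analytic: toe-slope at transition = dF * nu / nll = dF / dl = linear
    expect_equal(see$nu_see, nll / dl)
  }
})

test_that("Young's modulus is the linear-branch slope and scales correctly", {
  sigma <- 30e6
  E_tuned <- see_young_modulus(tuned_see(), 100, 100 / sigma)
  E_default <- see_young_modulus(see_params(), 100, 100 / sigma)
  expect_equal(E_tuned, 2.4e9)
  expect_equal(E_default / 1e9, 0.7, tolerance = 0.01)
  # doubling csa at fixed Fmax halves E
  expect_equal(see_young_modulus(tuned_see(), 100, 2 * 100 / sigma),
               E_tuned / 2)
  # invariance under simultaneous rescaling
  expect_equal(see_young_modulus(tuned_see(), 500, 500 / sigma), E_tuned)
  # tuned/default ratio matches the printed 2.4 / 0.7 moduli within 1%
  expect_equal(E_tuned / E_default, (0.8 / 0.01) / (0.4 / 0.017))
  expect_equal(E_tuned / E_default, 2.4 / 0.7, tolerance = 0.01)
})

test_that("isometric force-length factor has the bell shape", {
  ce <- ce_params(l_ce_opt = 0.05)
  expect_equal(ce_isometric_factor(ce, 0.05), 1)
  ce1 <- ce_params(l_ce_opt = 0.05, nu_desc = 1)
  expect_equal(ce_isometric_factor(ce1, 0.05 * (1 + ce1$dW_desc)), exp(-1))
  expect_lt(ce_isometric_factor(ce, 0.2 * 0.05), 0.05)
  # monotone on each branch
  asc <- ce_isometric_factor(ce, seq(0.02, 0.05, length.out = 30))
  desc <- ce_isometric_factor(ce, seq(0.05, 0.09, length.out = 30))
  expect_true(all(diff(asc) > 0))
  expect_true(all(diff(desc) < 0))
})

test_that("activation dynamics follow the exact exponential update", {
  act <- activation_params(tau_act = 0.01)
  expect_equal(activation_step(act, 0.4, 0.4, 0.01), 0.4)   # fixed point
  expect_equal(activation_step(act, 0, 1, 0.01), 1 - exp(-1),
               tolerance = 1e-12)
  expect_equal(activation_step(act, 1, 0, 100), act$a_min)  # decay floor
  # monotone in u, bounded in [a_min, 1]
  set.seed(7)
  for (i in 1:50) {
    a <- runif(1); dt <- runif(1, 1e-4, 0.1)
    u <- sort(runif(2))
    r1 <- activation_step(act, a, u[1], dt)
    r2 <- activation_step(act, a, u[2], dt)
    expect_lte(r1, r2)
    expect_gte(r1, act$a_min); expect_lte(r2, 1)
  }
})

test_that("initial length equilibrium applies the flexor/extensor scaling", {
  eqf <- init_equilibrium(0.300, 0.070, "flexor")
  expect_equal(eqf$l_see_0, 1.05 * 0.300 - 0.070)
  expect_equal(eqf$l_ce_i, 0.070)
  eqe <- init_equilibrium(0.300, 0.070, "extensor")
  expect_equal(eqe$l_see_0, 0.95 * 0.300 - 0.070)
  # the scaled decomposition holds exactly
  expect_equal(1.05 * 0.300, eqf$l_ce_i + eqf$l_see_0)
  expect_error(init_equilibrium(0.300, 0.32, "flexor", name = "FDP 2"),
               "FDP 2")
})

test_that("strand force scaling splits and recovers the whole-muscle force", {
  expect_equal(scale_fmax(strand_spec(1000, 4)), 250)
  expect_equal(scale_fmax(strand_spec(777, 1)), 777)
  expect_equal(scale_fmax(strand_spec(333, 3)) * 3, 333)
  expect_error(strand_spec(1000, 0), "positive integer")
})

test_that("static MTU outputs expose tendon strain and transmitted force", {
  eq <- init_equilibrium(0.300, 0.070, "flexor")
  see <- see_params(0.8, 0.02, 0.01, eq$l_see_0)
  m <- mtu_params("FDP 2", 100, 100 / 30e6, see, ce_params(0.070),
                  group = "flexor")
  s0 <- mtu_state(0.5, 0.070, 0.070 + eq$l_see_0)
  out0 <- mtu_outputs(m, s0)
  expect_equal(out0$eps_see, 0)
  expect_equal(out0$F_mtu, 0)
  s1 <- mtu_state(0.5, 0.070, 0.070 + eq$l_see_0 * 1.02)
  out1 <- mtu_outputs(m, s1)
  expect_equal(out1$F_mtu, 0.8 * 100)
  s2 <- mtu_state(0.5, 0.070, 0.070 + eq$l_see_0 * 0.99)
  out2 <- mtu_outputs(m, s2)
  expect_equal(out2$eps_see, -0.01)
  expect_equal(out2$F_mtu, 0)
})

test_that("contraction rate solves the series force balance", {
  eq <- init_equilibrium(0.300, 0.070, "flexor")
  see <- see_params(0.8, 0.02, 0.01, eq$l_see_0)
  m <- mtu_params("FDP 2", 100, 100 / 30e6, see, ce_params(0.070),
                  group = "flexor")
  # construct an exact equilibrium: pick strain, solve activation
  l_ce <- 0.070
  eps <- 0.005
  F_see <- see_force(see, 100, eq$l_see_0 * (1 + eps))
  a_eq <- F_see / (100 * ce_isometric_factor(m$ce, l_ce))
  s <- mtu_state(a_eq, l_ce, l_ce + eq$l_see_0 * (1 + eps))
  expect_equal(contraction_rate(m, s, v_mtu = 0), 0, tolerance = 1e-9)
  # raising activation above equilibrium shortens the fiber
  s_hi <- mtu_state(min(1, a_eq * 1.5), l_ce, s$l_mtu)
  expect_lt(contraction_rate(m, s_hi, 0), 0)
  # a fast stretch at minimum activation lengthens the fiber and the MTU
  # force rises above the isometric level
  s_lo <- mtu_state(0.005, l_ce, l_ce + eq$l_see_0 * 1.005)
  v <- contraction_rate(m, s_lo, v_mtu = 0.5)
  expect_gt(v, 0)
  F_tot <- see_force(see, 100, s_lo$l_mtu - l_ce) + m$d_se * (0.5 - v)
  expect_gt(F_tot, 0.005 * 100 * ce_isometric_factor(m$ce, l_ce))
})

test_that("contraction rate matches brute-force and closed-form solutions", {
  eq <- init_equilibrium(0.300, 0.070, "flexor")
  see <- see_params(0.8, 0.02, 0.01, eq$l_see_0)
  m <- mtu_params("FDP 2", 100, 100 / 30e6, see, ce_params(0.070),
                  group = "flexor")
  set.seed(21)
  for (i in 1:50) {
    l_ce <- 0.070 * runif(1, 0.9, 1.1)
    l_mtu <- eq$l_see_0 * (1 + runif(1, -0.004, 0.018)) + l_ce
    s <- mtu_state(runif(1, 0.5, 1), l_ce, l_mtu)
    v_mtu <- runif(1, -0.15, 0.15)
    v_root <- contraction_rate(m, s, v_mtu)
    v_brute <- brute_force_vce(m, s, v_mtu)
    expect_equal(v_root, v_brute, tolerance = 1e-8)
    F_see <- see_force(see, 100, max(l_mtu - l_ce, 0))
    F_pee <- pee_force(m$pee, m$ce, 100, l_ce)
    M <- s$a * 100 * ce_isometric_factor(m$ce, l_ce)
    v_closed <- fiber_velocity(F_see, F_pee, M, m$ce, 0.070, m$d_se, v_mtu)
    expect_equal(v_root, v_closed, tolerance = 1e-8)
  }
})

test_that("isometric hold converges to a balanced fixed point", {
  eq <- init_equilibrium(0.300, 0.070, "flexor")
  see <- see_params(0.8, 0.02, 0.01, eq$l_see_0)
  m <- mtu_params("FDP 2", 100, 100 / 30e6, see, ce_params(0.070),
                  group = "flexor")
  l_mtu <- 0.070 + eq$l_see_0          # constant path length
  a <- 0.005; u <- 0.6; l_ce <- 0.070
  dt <- 5e-4
  for (k in 1:2000) {
    a <- activation_step(m$act, a, u, dt)
    s <- mtu_state(a, l_ce, l_mtu)
    l_ce <- l_ce + dt * contraction_rate(m, s, v_mtu = 0)
  }
  resid <- jfisim:::mtu_force_residual(m, mtu_state(a, l_ce, l_mtu), 0, 0)
  expect_lt(abs(resid), 1e-6 * m$Fmax)
})
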