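# Tendon stress-strain modelling, windowed NMAE scoring and parameter
# fitting against synthetic reference curves.

test_that("model stress-strain curve hits the transition point exactly", {
  grid <- seq(0, 0.05, by = 1e-3)
  cv <- model_stress_strain(tuned_see(), 100, 100 / 30e6, grid)
  expect_equal(cv$stresses[cv$strains == 0], 0)
  expect_equal(cv$stresses[cv$strains == 0.02], 0.8 * 30e6)
  expect_true(all(diff(cv$stresses) >= 0))
  # linear-branch slope equals the Young's modulus
  lin <- cv$strains >= 0.02
  slope <- diff(cv$stresses[lin]) / diff(cv$strains[lin])
  expect_equal(mean(slope), see_young_modulus(tuned_see(), 100, 100 / 30e6),
               tolerance = 1e-10)
})

test_that("windowed NMAE behaves like the restricted curve NMAE", {
  grid <- seq(0, 0.05, by = 1e-3)
  ref <- model_stress_strain(tuned_see(), 100, 100 / 30e6, grid)
  ref <- stress_strain_curve(ref$strains, ref$stresses, "reference")
  expect_equal(windowed_nmae(ref, ref, 0.03), 0)
  over <- stress_strain_curve(ref$strains, 1.1 * ref$stresses, "model")
  expect_equal(windowed_nmae(over, ref, 0.03), 10, tolerance = 1e-8)
  expect_error(windowed_nmae(over, ref, 0.2), "cover")
})

test_that("a necking reference makes the wide window score worse", {
  # reference in the tendon model family up to 3.5% strain, necking beyond
  spec <- default_tendon_spec(linear_modulus = 2.4e9, toe_end_strain = 0.02,
                              linear_end_strain = 0.035,
                              necking_modulus_fraction = 0.15)
  ref <- gen_tendon_reference(spec)
  model <- model_stress_strain(tuned_see(), 100, 100 / 30e6, ref$strains)
  n3 <- windowed_nmae(model, ref, 0.03)
  n5 <- windowed_nmae(model, ref, 0.05)
  expect_gt(n5, n3)
})

test_that("the fit recovers generating parameters from a noise-free curve", {
  spec <- default_tendon_spec(linear_modulus = 2.4e9, toe_end_strain = 0.02,
                              necking_modulus_fraction = 1)
  ref <- gen_tendon_reference(spec)
  fit <- fit_see(ref, 100, 100 / 30e6, init = see_params())
  expect_equal(fit$see$dF_see_0_frac, 0.8, tolerance = 0.01)
  expect_equal(fit$see$dU_see_nll, 0.02, tolerance = 0.01)
  expect_equal(fit$see$dU_see_l, 0.01, tolerance = 0.01)
  expect_lt(fit$nmae3, 0.1)
  expect_lt(fit$nmae3, fit$nmae3_init)
  expect_equal(fit$E / 1e9, 2.4, tolerance = 0.01)
})

test_that("starting at the generating parameters is a fixed point", {
  spec <- default_tendon_spec(linear_modulus = 2.4e9, toe_end_strain = 0.02,
                              necking_modulus_fraction = 1)
  ref <- gen_tendon_reference(spec)
  fit <- fit_see(ref, 100, 100 / 30e6, init = tuned_see())
  expect_lt(fit$nmae3, 1e-6)
  expect_lt(fit$nmae5, 1e-6)
})

test_that("fitting a necking reference overestimates beyond the window", {
  spec <- default_tendon_spec(linear_modulus = 2.4e9, toe_end_strain = 0.015,
                              linear_end_strain = 0.035,
                              necking_modulus_fraction = 0.15)
  ref <- gen_tendon_reference(spec)
  fit <- fit_see(ref, 100, 100 / 30e6, init = see_params())
  expect_gt(fit$nmae5, fit$nmae3)
  # the fitted linear model overshoots the necked reference at 5% strain
  m5 <- model_stress_strain(fit$see, 100, 100 / 30e6, c(0.049, 0.05))
  r5 <- ref$stresses[which.min(abs(ref$strains - 0.05))]
  expect_gt(m5$stresses[2], r5)
})

test_that("the fit is invariant under simultaneous Fmax/csa rescaling", {
  spec <- default_tendon_spec(linear_modulus = 2.4e9, toe_end_strain = 0.02,
                              necking_modulus_fraction = 1)
  ref <- gen_tendon_reference(spec)
  f1 <- fit_see(ref, 100, 100 / 30e6, init = see_params())
  f2 <- fit_see(ref, 700, 700 / 30e6, init = see_params())
  expect_equal(f1$see$dF_see_0_frac, f2$see$dF_see_0_frac, tolerance = 1e-8)
  expect_equal(f1$see$dU_see_nll, f2$see$dU_see_nll, tolerance = 1e-8)
  expect_equal(f1$see$dU_see_l, f2$see$dU_see_l, tolerance = 1e-8)
  expect_equal(f1$E, f2$E, tolerance = 1e-8)
})
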