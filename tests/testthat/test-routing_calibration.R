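# NMAE metrics, via-point routing optimization and fit summaries.

test_that("MAE/NMAE follow their definitions", {
  expect_equal(nmae(c(1, 2, 3), c(1, 2, 3)), list(mae = 0, nmae_pct = 0))
  r <- nmae(c(2, 2, 3), c(1, 2, 3))
  expect_equal(r$mae, 1 / 3)
  expect_equal(r$nmae_pct, 100 * (1 / 3) / 2, tolerance = 1e-12)
  # the single-point deviation 9.7 +/- 2.0 mm corresponds to 20.62%
  r2 <- nmae(11.7, 9.7)
  expect_equal(r2$mae, 2.0)
  expect_equal(round(r2$nmae_pct, 2), 20.62)
  expect_error(nmae(c(1, -1), c(1, -1)), "zero")
})

test_that("NMAE is invariant under common positive rescaling", {
  set.seed(5)
  for (i in 1:20) {
    y <- runif(10, 1, 5); yh <- y + rnorm(10, 0, 0.3)
    c0 <- runif(1, 0.01, 100)
    expect_equal(nmae(yh, y)$nmae_pct, nmae(c0 * yh, c0 * y)$nmae_pct,
                 tolerance = 1e-10)
  }
})

test_that("fit summaries count curves below thresholds", {
  s <- summarize_fit(c(0.79, 3.0, 4.9, 23.72), thresholds = c(5, 25))
  expect_equal(s$min, 0.79)
  expect_equal(s$max, 23.72)
  expect_equal(unname(s$count_below["below_5pct"]), 3)
  expect_equal(unname(s$count_below["below_25pct"]), 4)
  s2 <- summarize_fit(rep(2, 5), thresholds = 2)
  expect_equal(s2$min, s2$max)
  expect_equal(unname(s2$count_below), 0)
  s3 <- summarize_fit(c(1, 2), thresholds = numeric(0))
  expect_equal(s3$min, 1); expect_equal(s3$max, 2)
  expect_length(s3$count_below, 0)
})

test_that("routing optimization recovers known via points from noise-free references", {
  model <- gen_hand_fixture()
  refs <- model_moment_arm_curves(model)          # truth
  refs <- lapply(refs, function(cv) {
    moment_arm_curve(cv$digit, cv$muscle, cv$joint, cv$angles, cv$arms,
                     "reference")
  })
  # perturb the wrap radii by +/- 20% as the starting point
  perturbed <- model
  set.seed(17)
  true_radii <- list()
  for (nm in names(perturbed$paths)) {
    p <- perturbed$paths[[nm]]
    if (!grepl("^(FDP|FDS)", nm)) next
    r0 <- jfisim:::get_path_radii(p)
    true_radii[[nm]] <- r0
    perturbed$paths[[nm]] <- jfisim:::set_path_radii(
      p, r0 * runif(length(r0), 0.8, 1.2))
  }
  perturbed$scene <- jfisim:::build_scene(perturbed)
  all_nmae <- c(); fitted <- perturbed
  for (muscle in c("FDP", "FDS")) {
    keep <- vapply(refs, function(cv) cv$muscle == muscle, TRUE)
    fit <- optimize_routing(fitted, muscle, refs[keep], n_starts = 1)
    fitted <- fit$model
    all_nmae <- c(all_nmae, fit$nmae_pct)
    for (nm in names(fit$radii)) {
      expect_equal(fit$radii[[nm]], unname(true_radii[[nm]]),
                   tolerance = 1e-3)
    }
  }
  expect_length(all_nmae, 20)
  expect_true(all(all_nmae < 1))
})

test_that("an already-optimal start stays at the fixed point", {
  model <- gen_hand_fixture()
  refs <- model_moment_arm_curves(model, muscles = "FDS")
  refs <- lapply(refs, function(cv) {
    moment_arm_curve(cv$digit, cv$muscle, cv$joint, cv$angles, cv$arms,
                     "reference")
  })
  fit <- optimize_routing(model, "FDS", refs, n_starts = 1)
  expect_true(all(fit$nmae_pct < 1e-6))
})

test_that("bounds excluding the truth give a best-in-bounds solution", {
  model <- gen_hand_fixture()
  refs <- model_moment_arm_curves(model, muscles = "FDS")
  refs <- lapply(refs, function(cv) {
    moment_arm_curve(cv$digit, cv$muscle, cv$joint, cv$angles, cv$arms,
                     "reference")
  })
  bounds <- c(0.012, 0.02)  # truth (11 and 6 mm radii) partly outside
  fit <- optimize_routing(model, "FDS", refs, bounds = bounds, n_starts = 1)
  for (nm in names(fit$radii)) {
    expect_true(all(fit$radii[[nm]] >= bounds[1] - 1e-12))
    expect_true(all(fit$radii[[nm]] <= bounds[2] + 1e-12))
  }
})

test_that("noisy references give an NMAE spread spanning good and poor fits", {
  model <- gen_hand_fixture()
  truth <- model_moment_arm_curves(model)
  # heterogeneous measurement scatter: 2% to 15% of the curve mean
  sds <- seq(0.02, 0.15, length.out = length(truth))
  refs <- jfisim:::with_seed(99, lapply(seq_along(truth), function(i) {
    cv <- truth[[i]]
    noisy <- cv$arms + stats::rnorm(length(cv$arms),
                                    0, sds[i] * mean(cv$arms))
    moment_arm_curve(cv$digit, cv$muscle, cv$joint, cv$angles, noisy,
                     "reference")
  }))
  names(refs) <- names(truth)
  all_nmae <- c(); fitted <- model
  for (muscle in c("FDP", "FDS")) {
    keep <- vapply(refs, function(cv) cv$muscle == muscle, TRUE)
    fit <- optimize_routing(fitted, muscle, refs[keep], n_starts = 1)
    fitted <- fit$model
    all_nmae <- c(all_nmae, fit$nmae_pct)
  }
  # spans roughly the sub-5% to ~25% range seen for real reference data
  expect_lt(min(all_nmae), 5)
  expect_gt(max(all_nmae), 5)
  expect_lt(max(all_nmae), 40)
})
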