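test_that("fixed-exponent fitting recovers generating parameters exactly", {
  law0 <- force_law(3, 5)
  r <- seq(0.9, 2.5, length.out = 40)
  fit <- fit_force_law(interaction_curve(r, force = lj_force(law0, r)))
  expect_rel_equal(c(fit$A, fit$B), c(3, 5), 1e-6)
  expect_true(attr(fit, "converged"))
  expect_lt(attr(fit, "sse"), 1e-12)
})

test_that("free-exponent fitting recovers all four parameters", {
  law0 <- force_law(3, 5, m = 15, n = 8)
  r_eq <- law_r_eq_any(law0)
  r <- seq(0.85 * r_eq, 2.5 * r_eq, length.out = 60)
  fit <- fit_force_law(interaction_curve(r, force = lj_force(law0, r)),
                       fix_exponents = FALSE)
  expect_rel_equal(c(fit$m, fit$n), c(15, 8), 1e-4)
  expect_rel_equal(c(fit$A, fit$B), c(3, 5), 1e-3)
})

test_that("free fit never does worse than the fixed fit", {
  cu <- gen_interaction_curve("V23-V23", "WT", noise_sd = 0.05, seed = 3,
                              defaults = test_defaults())
  sse_fixed <- attr(fit_force_law(cu, fix_exponents = TRUE), "sse")
  sse_free <- attr(fit_force_law(cu, fix_exponents = FALSE), "sse")
  expect_lte(sse_free, sse_fixed * (1 + 1e-9))
})

test_that("noisy fixed fits recover B with small median error (Monte Carlo)", {
  law0 <- law_from_well(2, 6)
  r <- seq(0.8 * 6, 3 * 6, length.out = 50)
  f0 <- lj_force(law0, r)
  # 5% of the peak (attractive) force of the well
  sd_f <- 0.05 * abs(min(f0))
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    fit <- fit_force_law(interaction_curve(r, force = f0 + rnorm(50, 0, sd_f)))
    abs(fit$B - law0$B) / law0$B
  }, 0)
  expect_lt(median(errs), 0.05)
})

test_that("energy-only curves are differentiated before fitting", {
  law0 <- force_law(3, 5)
  r <- seq(0.9, 2.5, length.out = 600)
  fit <- fit_force_law(interaction_curve(r, energy = lj_energy(law0, r)))
  # central differencing limits accuracy; parameters still close
  expect_rel_equal(fit$B, 5, 0.05)
})

test_that("fitting commutes with strength reduction on noiseless data", {
  cu <- gen_interaction_curve("L19-L19", "WT", defaults = test_defaults())
  fit_then_scale <- apply_reduction(fit_force_law(cu), 0.4)
  scaled <- interaction_curve(cu$distance, force = 0.6 * cu$force)
  scale_then_fit <- fit_force_law(scaled)
  expect_rel_equal(c(fit_then_scale$A, fit_then_scale$B),
                   c(scale_then_fit$A, scale_then_fit$B), 1e-9)
})

test_that("peak_to_peak_reduction handles identity, scaling, and errors", {
  r <- seq(4, 15, length.out = 50)
  law <- law_from_well(2, 6)
  wt <- interaction_curve(r, energy = lj_energy(law, r))
  expect_equal(peak_to_peak_reduction(wt, wt), 0)
  half <- interaction_curve(r, energy = 0.5 * lj_energy(law, r))
  expect_equal(peak_to_peak_reduction(wt, half), 50)
  deeper <- interaction_curve(r, energy = 2 * lj_energy(law, r))
  expect_lt(peak_to_peak_reduction(wt, deeper), 0)
  flat <- interaction_curve(r, energy = rep(0, 50))
  expect_error(peak_to_peak_reduction(flat, wt), "zero well depth")
})

test_that("interaction_curve validates its invariants", {
  expect_error(interaction_curve(c(1, 2), NULL, NULL), "at least one")
  expect_error(interaction_curve(c(2, 1), energy = c(1, 2)),
               "strictly increasing")
  expect_error(interaction_curve(c(-1, 2), energy = c(1, 2)), "> 0")
  expect_error(interaction_curve(c(1, 2), energy = c(1, NA)), "finite")
  expect_error(interaction_curve(c(1, 2), energy = 1), "lengths differ")
})

test_that("force/energy consistency validator accepts matched channels", {
  law <- law_from_well(1.5, 5)
  r <- seq(4, 15, length.out = 200)
  cu <- interaction_curve(r, energy = lj_energy(law, r),
                          force = lj_force(law, r))
  expect_true(validate_curve_consistency(cu))
  bad <- interaction_curve(r, energy = lj_energy(law, r),
                           force = -lj_force(law, r) + 5)
  expect_false(validate_curve_consistency(bad))
})
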