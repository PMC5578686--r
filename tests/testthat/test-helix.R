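test_that("engineering strain reproduces the published elongation pairs", {
  # reference length inferred from the (60.0 A, 20%) pair: L0 = 50 A
  L0 <- 60 / 1.2
  expect_equal(L0, 50)
  expect_equal(engineering_strain(60.0, L0), 0.20)
  expect_equal(engineering_strain(63.5, L0), 0.27)
  expect_equal(engineering_strain(64.5, L0), 0.29)
  expect_equal(engineering_strain(68.5, L0), 0.37)
  expect_equal(engineering_strain(72.0, L0), 0.44)
  expect_equal(engineering_strain(50, 50), 0)
  expect_error(engineering_strain(50, 0), "> 0")
})

test_that("axial stress follows force over rod cross-section", {
  expect_equal(axial_stress(0, 2.5), 0)
  r <- 2.5
  expect_equal(axial_stress(pi * r^2, r), 1)
  # 196.3 pN over a 2.5 A rod is ~10 pN/A^2, i.e. ~1 GPa
  expect_equal(pN_A2_to_MPa(axial_stress(196.3, 2.5)), 1000, tolerance = 1e-3)
  expect_error(axial_stress(10, -1), "> 0")
})

test_that("unit conversions round-trip", {
  x <- c(0.1, 1, 840)
  expect_equal(pN_to_kcalmol_per_A(kcalmol_per_A_to_pN(x)), x,
               tolerance = 1e-12)
  expect_equal(MPa_to_pN_A2(pN_A2_to_MPa(x)), x)
  expect_equal(kcalmol_per_A_to_pN(1), 69.48)
  expect_equal(pN_A2_to_MPa(10), 1000)
})

test_that("youngs_modulus recovers exact linear data and subsampling", {
  eps <- seq(0, 0.06, length.out = 40)
  cu <- stress_strain_curve("TM1", eps, 22 * eps)
  expect_rel_equal(youngs_modulus(cu), 22, 1e-9)
  sub <- stress_strain_curve("TM1", eps[seq(1, 40, by = 3)],
                             22 * eps[seq(1, 40, by = 3)])
  expect_rel_equal(youngs_modulus(sub), 22, 1e-9)
  expect_error(youngs_modulus(stress_strain_curve("N", c(0, 0.01), c(0, 1))),
               ">= 3 samples")
})

test_that("youngs_modulus recovery under noise (Monte Carlo)", {
  d <- test_defaults()
  E_true <- d$helices$TM1$E
  errs <- vapply(1:100, function(s) {
    cu <- gen_stress_strain("TM1", 0.06, noise_sd = 0.05 * E_true * 0.06,
                            seed = s, n_points = 30, defaults = d)
    abs(youngs_modulus(cu) - E_true) / E_true
  }, 0)
  expect_lt(median(errs), 0.05)
})

test_that("elastic_limit finds a programmed knee and reports no break", {
  # bilinear loading with knee at (elongation 7.5, force 200)
  el <- seq(0, 15, length.out = 61)
  fo <- ifelse(el <= 7.5, 200 / 7.5 * el, 200 + 0.1 * 200 / 7.5 * (el - 7.5))
  lim <- elastic_limit(cbind(el, fo), reference_length = 50)
  expect_true(lim$reached)
  expect_equal(lim$force, 200, tolerance = 1e-6)
  expect_equal(lim$strain, 0.15, tolerance = 1e-6)
  linear <- elastic_limit(cbind(el, 30 * el), reference_length = 50)
  expect_false(linear$reached)
})

test_that("reversibility classification matches residual elongation", {
  d <- test_defaults()
  el29 <- classify_reversibility(gen_load_unload("TM1", 0.29, defaults = d))
  expect_identical(el29$class, "elastic")
  expect_lt(abs(el29$residual), 1e-9)
  pl37 <- classify_reversibility(gen_load_unload("TM1", 0.37, defaults = d))
  expect_identical(pl37$class, "plastic")
  expect_equal(pl37$residual, 4, tolerance = 1e-9)
  zero <- classify_reversibility(gen_load_unload("TM1", 0, defaults = d))
  expect_identical(zero$class, "elastic")
  expect_equal(zero$residual, 0)
})

test_that("reversibility is monotone in peak strain", {
  d <- test_defaults()
  classes <- vapply(seq(0.05, 0.45, by = 0.05), function(p)
    classify_reversibility(gen_load_unload("TM1", p, defaults = d))$class, "")
  # once plastic, never back to elastic
  first_plastic <- match("plastic", classes)
  expect_false(anyNA(first_plastic))
  expect_true(all(classes[first_plastic:length(classes)] == "plastic"))
})

test_that("trace TSV round-trips preserve both container types", {
  d <- test_defaults()
  ss <- gen_stress_strain("TM2", 0.05, noise_sd = 0.1, seed = 4, defaults = d)
  tf <- tempfile(fileext = ".tsv")
  write_trace_file(ss, tf)
  ss2 <- read_stress_strain_file(tf, "TM2")
  expect_equal(ss2$strain, ss$strain, tolerance = 1e-10)
  expect_equal(ss2$stress, ss$stress, tolerance = 1e-10)
  lu <- gen_load_unload("TM1", 0.37, defaults = d)
  tf2 <- tempfile(fileext = ".tsv")
  write_trace_file(lu, tf2)
  lu2 <- read_load_unload_file(tf2, "TM1")
  expect_equal(lu2$elongation, lu$elongation, tolerance = 1e-10)
  expect_identical(lu2$peak_index, lu$peak_index)
  expect_identical(classify_reversibility(lu2)$class, "plastic")
})
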