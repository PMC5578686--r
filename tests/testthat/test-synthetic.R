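test_that("noiseless curves reproduce their configured well exactly", {
  d <- test_defaults()
  for (b in d$belts$belt) {
    cu <- gen_interaction_curve(b, "WT", noise_sd = 0, defaults = d)
    i <- match(b, d$belts$belt)
    expect_equal(min(cu$energy), -d$belts$depth_wt[i], tolerance = 1e-12)
    expect_equal(cu$distance[which.min(cu$energy)], d$belts$r_eq[i],
                 tolerance = 1e-12)
  }
})

test_that("G22N curves scale and shift as configured", {
  d <- test_defaults()
  # no reduction for A20-G22: well depth equals WT
  wt <- gen_interaction_curve("A20-G22", "WT", defaults = d)
  mu <- gen_interaction_curve("A20-G22", "G22N", defaults = d)
  expect_equal(min(mu$energy), min(wt$energy), tolerance = 1e-12)
  # equilibrium right-shift present for shifted belts
  i <- match("A20-G22", d$belts$belt)
  expect_equal(mu$distance[which.min(mu$energy)],
               d$belts$r_eq[i] + d$belts$g22n_shift[i], tolerance = 1e-12)
  # L19-L19 depth ratio 0.57
  wtl <- gen_interaction_curve("L19-L19", "WT", defaults = d)
  mul <- gen_interaction_curve("L19-L19", "G22N", defaults = d)
  expect_equal(min(mul$energy) / min(wtl$energy), 0.57, tolerance = 1e-12)
})

test_that("unknown pairs, genotypes and bad arguments are rejected", {
  d <- test_defaults()
  expect_error(gen_interaction_curve("V99-X1", "WT", defaults = d),
               "unknown belt 'V99-X1'")
  expect_error(gen_interaction_curve("L19-L19", "XYZ", defaults = d))
  expect_error(gen_interaction_curve("L19-L19", "WT", n_points = 5,
                                     defaults = d), "n_points")
  expect_error(gen_interaction_curve("L19-L19", "WT", noise_sd = -0.1,
                                     defaults = d), "noise_sd")
  expect_error(gen_stress_strain("Q", 0.05, defaults = d))
  expect_error(gen_stress_strain("N", 0.9, defaults = d), "max_strain")
})

test_that("equal seeds give bitwise-identical noisy output", {
  d <- test_defaults()
  a <- gen_interaction_curve("V23-V23", "WT", noise_sd = 0.05, seed = 42,
                             defaults = d)
  b <- gen_interaction_curve("V23-V23", "WT", noise_sd = 0.05, seed = 42,
                             defaults = d)
  expect_identical(a$energy, b$energy)
  expect_identical(a$force, b$force)
  c2 <- gen_interaction_curve("V23-V23", "WT", noise_sd = 0.05, seed = 43,
                              defaults = d)
  expect_false(identical(a$energy, c2$energy))
  s1 <- gen_stress_strain("TM1", 0.06, noise_sd = 0.05, seed = 7, defaults = d)
  s2 <- gen_stress_strain("TM1", 0.06, noise_sd = 0.05, seed = 7, defaults = d)
  expect_identical(s1$stress, s2$stress)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- runif(1)
  set.seed(1234)
  invisible(gen_interaction_curve("L19-L19", "WT", noise_sd = 0.1, seed = 9,
                                  defaults = test_defaults()))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("stress-strain curves are bilinear with the configured moduli", {
  d <- test_defaults()
  cu <- gen_stress_strain("TM1", 0.06, defaults = d)
  expect_rel_equal(youngs_modulus(cu), d$helices$TM1$E, 1e-9)
  # beyond yield the slope drops to the plastic fraction
  cu2 <- gen_stress_strain("TM1", 0.45, n_points = 200, defaults = d)
  late <- cu2$strain > 0.35
  slope_late <- coef(lm(cu2$stress[late] ~ cu2$strain[late]))[2]
  expect_rel_equal(unname(slope_late),
                   d$trace$plastic_slope_frac * d$helices$TM1$E, 1e-6)
})

test_that("helix stiffness ordering: C > TM1 ~ TM2 > 4x N", {
  d <- test_defaults()
  E <- vapply(c("N", "TM1", "TM2", "C"), function(h)
    youngs_modulus(gen_stress_strain(h, 0.06, defaults = d)), 0)
  expect_gt(E[["C"]], E[["TM1"]])
  expect_gt(E[["C"]], E[["TM2"]])
  expect_gt(E[["TM1"]] / E[["N"]], 4)
  expect_gt(E[["TM2"]] / E[["N"]], 4)
  expect_lt(abs(E[["TM1"]] - E[["TM2"]]) / E[["TM1"]], 0.2)
})

test_that("default TM1 load-unload trace yields at ~400 pN and ~30% strain", {
  lim <- elastic_limit(gen_load_unload("TM1", 0.45, defaults = test_defaults()))
  expect_true(lim$reached)
  expect_equal(lim$force, 400, tolerance = 1e-6)
  expect_equal(lim$strain, 0.30, tolerance = 1e-6)
})

test_that("geometry fixtures measure the reference pore diameters", {
  d <- test_defaults()
  expect_equal(pore_diameter(gen_geometry("WT", "closed", d$geometry)), 8,
               tolerance = 1e-9)
  expect_equal(pore_diameter(gen_geometry("G22N", "closed", d$geometry)), 11,
               tolerance = 1e-9)
  expect_equal(pore_diameter(gen_geometry("WT", "open-target", d$geometry)),
               28, tolerance = 1e-6)
  expect_equal(pore_diameter(gen_geometry("G22N", "open-target", d$geometry)),
               28, tolerance = 1e-6)
})

test_that("geometries are invariant under 72-degree rotation", {
  g <- gen_geometry("WT", "closed")
  th <- 2 * pi / 5
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  for (h in c("N", "TM1", "TM2", "C")) {
    rotated <- g$subunits[[1]][[h]][, 1:3] %*% t(R)
    expect_lt(max(abs(rotated - g$subunits[[2]][[h]][, 1:3])), 1e-9)
  }
})

test_that("helix polyline lengths match the rod specifications", {
  g <- gen_geometry("WT", "closed")
  lens <- c(N = 18.65, TM1 = 47.33, TM2 = 42.51, C = 36.06)
  for (h in names(lens)) {
    poly <- g$subunits[[4]][[h]]
    seg <- sum(sqrt(rowSums(diff(poly[, 1:3])^2)))
    expect_equal(seg, unname(lens[h]), tolerance = 1e-6)
  }
})
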