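test_that("connector counting: 25 wild-type, 5 per belt removed", {
  g <- gen_geometry("WT", "closed")
  d <- test_defaults()
  expect_identical(nrow(build_porelock(g, defaults = d)), 25L)
  expect_identical(nrow(build_porelock(g, deletions = "V23-G26",
                                       defaults = d)), 20L)
  expect_identical(nrow(build_porelock(g, deletions = c("V23-G26", "V16-G22"),
                                       defaults = d)), 15L)
  expect_identical(nrow(build_porelock(g, deletions = d$belts$belt,
                                       defaults = d)), 0L)
  for (nd in 0:2) {
    del <- d$belts$belt[seq_len(nd)]
    expect_identical(nrow(build_porelock(g, deletions = del, defaults = d)),
                     5L * (5L - nd))
  }
  expect_error(build_porelock(g, deletions = "X1-X2", defaults = d),
               "unknown belt")
})

test_that("laws must cover every non-deleted belt", {
  g <- gen_geometry("WT", "closed")
  d <- test_defaults()
  laws <- list("L19-L19" = law_from_well(1, 5))
  expect_error(build_porelock(g, laws = laws, defaults = d),
               "no force law")
})

test_that("rest-state connectors are at equilibrium and obey Newton's third law", {
  d <- test_defaults()
  g <- gen_geometry("WT", "closed")
  mesh <- discretize(g, defaults = d)
  conn <- build_porelock(g, defaults = d)
  cf <- connector_forces(conn, mesh)
  # equilibrium distances equal the closed anchor separations
  expect_lt(max(abs(cf$f)), 1e-9)
  # third law: exact cancellation, including off-equilibrium
  X <- mesh$X0 * 1.07
  cf2 <- connector_forces(conn, mesh, X)
  expect_true(any(abs(cf2$f) > 1))
  expect_lt(max(abs(cf2$on_a + cf2$on_b)), 1e-12)
  expect_lt(max(abs(colSums(cf2$on_a) + colSums(cf2$on_b))), 1e-9)
})

test_that("uniform reduction propagates to every connector", {
  d <- test_defaults()
  g <- gen_geometry("WT", "closed")
  conn <- build_porelock(g, rho = 0.5, defaults = d)
  full <- build_porelock(g, defaults = d)
  for (i in c(1, 10, 25))
    expect_rel_equal(law_well_depth(conn$law[[i]]),
                     0.5 * law_well_depth(full$law[[i]]), 1e-12)
})

test_that("scenario laws encode the eleven models correctly", {
  d <- test_defaults()
  s5 <- make_scenario(5)
  expect_identical(s5$pull, "n")
  expect_equal(s5$rho, 0.98)
  expect_length(s5$deletions, 0)
  s8 <- make_scenario(8)
  expect_identical(s8$deletions, "V16-G22")
  expect_equal(s8$rho, 0.5)
  expect_identical(s8$pull, "n+tm1")
  s11 <- make_scenario(11)
  expect_identical(s11$genotype, "G22N")
  laws11 <- scenario_laws(s11, d, g22n_shift = FALSE)
  wt <- scenario_laws(make_scenario(6), d)
  red <- d$belts$g22n_reduction[match(names(laws11), d$belts$belt)]
  got <- vapply(names(laws11), function(b)
    1 - law_well_depth(laws11[[b]]) / law_well_depth(wt[[b]]), 0)
  expect_equal(unname(got), red, tolerance = 1e-12)
  expect_error(make_scenario(12), "1..11")
})
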