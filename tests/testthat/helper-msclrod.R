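# shared fixtures: small meshes built in code, plus a cache so the
# eleven gating scenarios are solved once per test run

.scenario_env <- new.env(parent = emptyenv())

#' defaults shared by all scenario-level tests (the frozen study conditions)
test_defaults <- function() {
  if (is.null(.scenario_env$defaults))
    .scenario_env$defaults <- synthetic_defaults(seed = 1L)
  .scenario_env$defaults
}

get_scenario <- function(id, increments = 30L) {
  key <- sprintf("s%02d_i%d", id, increments)
  if (is.null(.scenario_env[[key]]))
    .scenario_env[[key]] <- run_scenario(id, defaults = test_defaults(),
                                         increments = increments,
                                         keep_trajectory = TRUE)
  .scenario_env[[key]]
}

# a single vertical rod mesh: base at origin, axis +z
single_rod_mesh <- function(L = 10, nel = 4, E = 22, radius = 2.5) {
  A <- pi * radius^2
  X <- cbind(0, 0, seq(0, L, length.out = nel + 1))
  pairs <- data.frame(a = 1:nel, b = 2:(nel + 1),
                      k = E * A / (L / nel), L0 = L / nel,
                      kind = "rod", helix = "TM1", subunit = 0,
                      E = E, area = A)
  bends <- if (nel >= 2)
    data.frame(i = 1:(nel - 1), j = 2:nel, k = 3:(nel + 1),
               kb = E * pi * radius^4 / 4 / (L / nel))
  else NULL
  mesh_from_parts(X, pairs, bends)
}

# two free particles joined by one connector
two_particle_mesh <- function(r0 = 3.2) {
  mesh_from_parts(matrix(c(0, 0, 0, r0, 0, 0), 2, 3, byrow = TRUE))
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_true(all(abs(actual - expected) <= rel_tol * abs(expected)),
              label = sprintf("%s vs %s (rel tol %g)",
                              paste(format(actual), collapse = ","),
                              paste(format(expected), collapse = ","),
                              rel_tol))
}
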