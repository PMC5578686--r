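test_that("solver gradient matches finite differences of the energy", {
  set.seed(5)
  X0 <- matrix(rnorm(15, sd = 3), 5, 3)
  pairs <- data.frame(a = 1:4, b = 2:5, k = c(5, 4, 3, 2), L0 = rep(2, 4),
                      kind = "rod", helix = "TM1", subunit = 0,
                      E = 22, area = pi * 6.25)
  bends <- data.frame(i = 1:3, j = 2:4, k = 3:5, kb = rep(7, 3))
  mesh <- mesh_from_parts(X0, pairs, bends)
  law <- law_from_well(2, 4)
  conn_idx <- data.frame(node_a = 1L, node_b = 5L)
  conn_idx$law <- list(law)
  X <- X0 + matrix(rnorm(15, sd = 0.2), 5, 3)
  g <- as.vector(t(msclrod:::.total_gradient(mesh, conn_idx, X)))
  h <- 1e-6
  for (q in sample(1:15, 6)) {
    Xp <- t(X); Xp[q] <- Xp[q] + h
    Xm <- t(X); Xm[q] <- Xm[q] - h
    fd <- (msclrod:::.total_energy(mesh, conn_idx, t(Xp)) -
             msclrod:::.total_energy(mesh, conn_idx, t(Xm))) / (2 * h)
    expect_lt(abs(g[q] - fd), 1e-6)
  }
})

test_that("two free particles settle at the law's equilibrium distance", {
  law <- law_from_well(2, 4)
  mesh <- two_particle_mesh(3.2)
  conn_idx <- data.frame(node_a = 1L, node_b = 2L)
  conn_idx$law <- list(law)
  eq <- msclrod:::.equilibrate(mesh, conn_idx, mesh$X0, 1:6, 1e-8, 100)
  sep <- sqrt(sum((eq$X[2, ] - eq$X[1, ])^2))
  # independent oracle: 1-D brute-force minimization of the potential
  oracle <- optimize(function(r) msclrod:::.connector_potential(law, r),
                     c(2, 12), tol = 1e-10)$minimum
  expect_lt(abs(sep - oracle), 1e-6)
  expect_lt(abs(sep - (2 * law$A / law$B)^(1 / 6)), 1e-6)
})

test_that("an axially stretched rod carries uniform stress E*delta/L", {
  L <- 10
  mesh <- single_rod_mesh(L = L, nel = 4, E = 22)
  bc <- boundary_conditions(fixed = 1, pulled = 5, targets = c(0, 0, 0.5),
                            increments = 5)
  traj <- solve_gating(mesh, NULL, bc)
  sig <- traj$steps[[length(traj$steps)]]$stress
  expect_rel_equal(sig, rep(22 * 0.5 / L, 4), 0.01)
  expect_true(all(vapply(traj$steps, `[[`, TRUE, "converged")))
})

test_that("zero prescribed displacement keeps zero stress and zero iterations", {
  mesh <- single_rod_mesh()
  bc <- boundary_conditions(fixed = 1, pulled = 5, targets = c(0, 0, 0),
                            increments = 2)
  traj <- solve_gating(mesh, NULL, bc)
  for (s in traj$steps) {
    expect_lt(max(abs(s$stress)), 1e-12)
    expect_identical(s$iterations, 0L)
  }
})

test_that("small models match direct numerical minimization of the energy", {
  # 4-node chain with a connector: solver vs L-BFGS-B from scratch
  X0 <- rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0), c(6, 0, 0))
  pairs <- data.frame(a = 1:3, b = 2:4, k = c(8, 6, 8), L0 = rep(2, 3),
                      kind = "rod", helix = "TM1", subunit = 0,
                      E = 22, area = 1)
  bends <- data.frame(i = 1:2, j = 2:3, k = 3:4, kb = c(3, 3))
  mesh <- mesh_from_parts(X0, pairs, bends)
  law <- law_from_well(1.5, 3)
  conn_idx <- data.frame(node_a = 1L, node_b = 4L)
  conn_idx$law <- list(law)
  # fix node 1, free nodes 2-4
  free <- as.vector(vapply(2:4, function(i) (i - 1L) * 3L + 1:3, integer(3)))
  eq <- msclrod:::.equilibrate(mesh, conn_idx, X0, free, 1e-9, 200)
  obj <- function(p) {
    X <- X0
    X[2:4, ] <- matrix(p, 3, 3, byrow = TRUE)
    msclrod:::.total_energy(mesh, conn_idx, X)
  }
  # the independent minimizer started at the solver's answer must not
  # move away or lower the energy (i.e. the answer is the basin minimum)
  p0 <- as.vector(t(eq$X[2:4, ]))
  op <- optim(p0, obj, method = "L-BFGS-B",
              control = list(maxit = 2000, factr = 10))
  expect_lt(max(abs(op$par - p0)), 1e-4)
  expect_gte(op$value, obj(p0) - 1e-8)
})

test_that("stress metrics equal a direct scan of programmed arrays", {
  # synthetic trajectory: programmed pore and stress sequences
  pairs <- data.frame(a = 1:3, b = 2:4,
                      k = 1, L0 = 1, kind = "rod",
                      helix = c("TM1", "TM1", "N"), subunit = 0,
                      E = 1, area = 1)
  mesh <- mesh_from_parts(matrix(0, 4, 3), pairs)
  pore <- c(8, 9, 16, 25, 27.5)
  tm1_stress <- rbind(c(0, 0), c(2, 4), c(5, 3), c(3, 1), c(1.5, 0.5))
  n_stress <- c(0, 1, 2, 1, 0.5)
  steps <- lapply(1:5, function(i)
    list(t = (i - 1) / 4, pore = pore[i],
         stress = c(tm1_stress[i, ], n_stress[i]),
         residual = 0, iterations = 1L, converged = TRUE))
  traj <- structure(list(steps = steps, mesh = mesh, truncated_at = NA),
                    class = "equilibrium_trajectory")
  m <- tm1_stress_metrics(traj)
  expect_true(m$opened)
  means <- rowMeans(abs(tm1_stress))
  expect_equal(m$threshold_MPa, 100 * max(means))
  expect_equal(m$open_state_MPa, 100 * means[5])
  # onset: first pore above 8 + 0.25 * (28 - 8) = 13
  expect_identical(m$onset_increment, 2L)
  expect_equal(unname(m$helix_max_MPa[["N"]]), 200)
  # constant-pore trajectory: not opened, metrics absent
  steps2 <- lapply(steps, function(s) { s$pore <- 8; s })
  m2 <- tm1_stress_metrics(structure(list(steps = steps2, mesh = mesh,
                                          truncated_at = NA),
                                     class = "equilibrium_trajectory"))
  expect_false(m2$opened)
  expect_true(is.na(m2$threshold_MPa))
  expect_true(is.na(m2$open_state_MPa))
})

test_that("reactions balance connector self-forces at equilibrium", {
  # total gradient over all nodes is the negative of total reactions;
  # at equilibrium the free-node gradient vanishes and the summed
  # gradient over constrained nodes equals the net external force = 0
  law <- law_from_well(2, 4)
  mesh <- two_particle_mesh(3.6)
  conn_idx <- data.frame(node_a = 1L, node_b = 2L)
  conn_idx$law <- list(law)
  eq <- msclrod:::.equilibrate(mesh, conn_idx, mesh$X0, 1:6, 1e-9, 100)
  G <- msclrod:::.total_gradient(mesh, conn_idx, eq$X)
  expect_lt(max(abs(colSums(G))), 1e-9)
})
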