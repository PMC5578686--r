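#' Nonlinear static equilibrium of the rod-and-connector model
#'
#' Displacement-controlled gating: prescribed nodes are moved along a
#' linear path in increments; at each increment the free nodes are
#' iterated to static equilibrium (internal elastic forces balancing
#' connector forces) by a damped Newton method on the total potential
#' energy, with the residual measured as the out-of-balance force on
#' the free degrees of freedom.
#'
#' @name fe-solver
NULL

.dof <- function(node, d) (node - 1L) * 3L + d

# connector potential in pN*A (force law integrated, with the
# short-range linear continuation matching connector_force)
.connector_potential <- function(law, r) {
  if (inherits(law, "zero_force_law")) return(rep(0, length(r)))
  rf <- 0.75 * law_r_eq_any(law)
  m <- law$m; n <- law$n
  Ucl <- function(x) .KCALMOL_PER_A_IN_PN *
    (12 * law$A / ((m - 1) * x^(m - 1)) - 6 * law$B / ((n - 1) * x^(n - 1)))
  out <- numeric(length(r))
  lo <- r < rf
  out[!lo] <- Ucl(r[!lo])
  if (any(lo)) {
    F0 <- connector_force(law, rf)
    S0 <- connector_force_slope(law, rf)
    dr <- r[lo] - rf
    out[lo] <- Ucl(rf) - F0 * dr - 0.5 * S0 * dr^2
  }
  out
}

# pair-spring state shared by energy/grad/hessian: for axial springs
# U' = k (l - L0), U'' = k; for connectors U' = -F(r), U'' = -dF/dr.
.pair_state <- function(mesh, connectors, conn_idx, X) {
  pr <- mesh$pairs
  a <- c(pr$a, conn_idx$node_a)
  b <- c(pr$b, conn_idx$node_b)
  d <- X[b, , drop = FALSE] - X[a, , drop = FALSE]
  l <- sqrt(rowSums(d^2))
  u <- d / l
  np <- nrow(pr)
  Up <- numeric(length(l)); Upp <- numeric(length(l))
  if (np) {
    Up[1:np] <- pr$k * (l[1:np] - pr$L0)
    Upp[1:np] <- pr$k
  }
  if (!is.null(conn_idx) && nrow(conn_idx)) {
    ci <- np + seq_len(nrow(conn_idx))
    for (j in seq_len(nrow(conn_idx))) {
      law <- conn_idx$law[[j]]
      Up[ci[j]] <- -connector_force(law, l[ci[j]])
      Upp[ci[j]] <- -connector_force_slope(law, l[ci[j]])
    }
  }
  list(a = a, b = b, l = l, u = u, Up = Up, Upp = Upp, np = np)
}

.pair_energy <- function(mesh, connectors, conn_idx, X) {
  pr <- mesh$pairs
  e <- 0
  if (nrow(pr)) {
    d <- X[pr$b, , drop = FALSE] - X[pr$a, , drop = FALSE]
    l <- sqrt(rowSums(d^2))
    e <- sum(0.5 * pr$k * (l - pr$L0)^2)
  }
  if (!is.null(conn_idx) && nrow(conn_idx)) {
    d <- X[conn_idx$node_b, , drop = FALSE] -
      X[conn_idx$node_a, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    for (j in seq_along(r))
      e <- e + .connector_potential(conn_idx$law[[j]], r[j])
  }
  e
}

# bending state: straight-rest discrete bending, E = kb (1 - cos theta)
.bend_terms <- function(bd, X) {
  u <- X[bd$j, , drop = FALSE] - X[bd$i, , drop = FALSE]
  v <- X[bd$k, , drop = FALSE] - X[bd$j, , drop = FALSE]
  lu <- sqrt(rowSums(u^2)); lv <- sqrt(rowSums(v^2))
  t1 <- u / lu; t2 <- v / lv
  cth <- rowSums(t1 * t2)
  list(t1 = t1, t2 = t2, lu = lu, lv = lv, cth = cth)
}

.bend_energy <- function(bd, X) {
  if (!nrow(bd)) return(0)
  bt <- .bend_terms(bd, X)
  sum(bd$kb * (1 - bt$cth))
}

# gradient of the bending energy for triples given as an n x 9 matrix
# (xi yi zi xj yj zj xk yk zk); vectorized over triples
.bend_grad_flat <- function(P, kb) {
  u <- P[, 4:6, drop = FALSE] - P[, 1:3, drop = FALSE]
  v <- P[, 7:9, drop = FALSE] - P[, 4:6, drop = FALSE]
  lu <- sqrt(rowSums(u^2)); lv <- sqrt(rowSums(v^2))
  t1 <- u / lu; t2 <- v / lv
  cth <- rowSums(t1 * t2)
  dci <- -(t2 - cth * t1) / lu
  dck <- (t1 - cth * t2) / lv
  dcj <- -dci - dck
  # E = kb (1 - c) => dE/dx = -kb * dc/dx
  cbind(-kb * dci, -kb * dcj, -kb * dck)
}

.total_energy <- function(mesh, conn_idx, X) {
  .pair_energy(mesh, NULL, conn_idx, X) + .bend_energy(mesh$bends, X)
}

.total_gradient <- function(mesh, conn_idx, X) {
  n <- nrow(X)
  G <- matrix(0, n, 3)
  st <- .pair_state(mesh, NULL, conn_idx, X)
  C <- st$u * st$Up  # force contribution on b (= -dU/dxa)
  acc <- function(G, idx, val) {
    o <- rowsum(val, group = idx, reorder = FALSE)
    rows <- as.integer(rownames(o))
    G[rows, ] <- G[rows, ] + o
    G
  }
  G <- acc(G, st$b, C)
  G <- acc(G, st$a, -C)
  bd <- mesh$bends
  if (nrow(bd)) {
    P <- cbind(X[bd$i, , drop = FALSE], X[bd$j, , drop = FALSE],
               X[bd$k, , drop = FALSE])
    gb <- .bend_grad_flat(P, bd$kb)
    G <- acc(G, bd$i, gb[, 1:3, drop = FALSE])
    G <- acc(G, bd$j, gb[, 4:6, drop = FALSE])
    G <- acc(G, bd$k, gb[, 7:9, drop = FALSE])
  }
  G
}

.total_hessian <- function(mesh, conn_idx, X) {
  n3 <- 3L * nrow(X)
  st <- .pair_state(mesh, NULL, conn_idx, X)
  coefA <- st$Upp - st$Up / st$l
  coefB <- st$Up / st$l
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (d1 in 1:3) for (d2 in 1:3) {
    val <- coefA * st$u[, d1] * st$u[, d2] + if (d1 == d2) coefB else 0
    for (s1 in c("a", "b")) for (s2 in c("a", "b")) {
      sgn <- if (s1 == s2) 1 else -1
      ii <- c(ii, .dof(st[[s1]], d1))
      jj <- c(jj, .dof(st[[s2]], d2))
      xx <- c(xx, sgn * val)
    }
  }
  bd <- mesh$bends
  if (nrow(bd)) {
    P <- cbind(X[bd$i, , drop = FALSE], X[bd$j, , drop = FALSE],
               X[bd$k, , drop = FALSE])
    h <- 1e-5
    gidx <- cbind(.dof(bd$i, 1), .dof(bd$i, 2), .dof(bd$i, 3),
                  .dof(bd$j, 1), .dof(bd$j, 2), .dof(bd$j, 3),
                  .dof(bd$k, 1), .dof(bd$k, 2), .dof(bd$k, 3))
    for (q in 1:9) {
      Pp <- P; Pp[, q] <- Pp[, q] + h
      Pm <- P; Pm[, q] <- Pm[, q] - h
      Hq <- (.bend_grad_flat(Pp, bd$kb) - .bend_grad_flat(Pm, bd$kb)) / (2 * h)
      for (p in 1:9) {
        ii <- c(ii, gidx[, p]); jj <- c(jj, gidx[, q]); xx <- c(xx, Hq[, p])
      }
    }
  }
  H <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n3, n3))
  (H + Matrix::t(H)) / 2
}

# damped (Levenberg) Newton on the free DOFs; returns list(X, residual,
# iterations, converged)
.equilibrate <- function(mesh, conn_idx, X, free_dof, tol, max_iter) {
  if (!length(free_dof))
    return(list(X = X, residual = 0, iterations = 0L, converged = TRUE))
  gvec <- function(X) as.vector(t(.total_gradient(mesh, conn_idx, X)))
  set_free <- function(X, xf) {
    Xt <- t(X); Xt[free_dof] <- xf; t(Xt)
  }
  get_free <- function(X) as.vector(t(X))[free_dof]

  E0 <- .total_energy(mesh, conn_idx, X)
  lambda <- 0
  iters <- 0L
  res <- max(abs(gvec(X)[free_dof]))
  while (res > tol && iters < max_iter) {
    iters <- iters + 1L
    g <- gvec(X)[free_dof]
    H <- as.matrix(.total_hessian(mesh, conn_idx, X)[free_dof, free_dof])
    dscale <- mean(abs(diag(H))) + 1e-12
    ok <- FALSE
    for (trial in 1:15) {
      Hd <- H
      if (lambda > 0) diag(Hd) <- diag(Hd) + lambda * dscale
      ch <- tryCatch(chol(Hd), error = function(e) NULL)
      if (is.null(ch)) {
        lambda <- max(lambda * 10, 1e-8)
        next
      }
      step <- -backsolve(ch, forwardsolve(t(ch), g))
      Xc <- set_free(X, get_free(X) + step)
      Ec <- .total_energy(mesh, conn_idx, Xc)
      resc <- max(abs(gvec(Xc)[free_dof]))
      if (is.finite(Ec) &&
          (Ec <= E0 + 1e-9 * (abs(E0) + 1) || resc < 0.9 * res)) {
        X <- Xc; E0 <- Ec; res <- resc
        lambda <- lambda / 5
        if (lambda < 1e-12) lambda <- 0
        ok <- TRUE
        break
      }
      lambda <- max(lambda * 10, 1e-8)
    }
    if (!ok) break
  }
  if (res > tol) {
    # quasi-Newton fallback, then report the polished residual
    xf <- get_free(X)
    op <- stats::optim(
      xf,
      fn = function(p) .total_energy(mesh, conn_idx, set_free(X, p)),
      gr = function(p) gvec(set_free(X, p))[free_dof],
      method = "L-BFGS-B",
      control = list(maxit = 500, factr = 1e4))
    Xc <- set_free(X, op$par)
    resc <- max(abs(gvec(Xc)[free_dof]))
    if (resc < res) { X <- Xc; res <- resc }
    # one last Newton pass from the improved point
    if (res > tol) {
      sub <- .equilibrate_newton_only(mesh, conn_idx, X, free_dof, tol,
                                      max(10L, max_iter %/% 4L))
      if (sub$residual < res) { X <- sub$X; res <- sub$residual }
      iters <- iters + sub$iterations
    }
  }
  list(X = X, residual = res, iterations = iters, converged = res <= tol)
}

.equilibrate_newton_only <- function(mesh, conn_idx, X, free_dof, tol,
                                     max_iter) {
  gvec <- function(X) as.vector(t(.total_gradient(mesh, conn_idx, X)))
  res <- max(abs(gvec(X)[free_dof]))
  iters <- 0L
  lambda <- 1e-6
  while (res > tol && iters < max_iter) {
    iters <- iters + 1L
    g <- gvec(X)[free_dof]
    H <- as.matrix(.total_hessian(mesh, conn_idx, X)[free_dof, free_dof])
    diag(H) <- diag(H) + lambda * (mean(abs(diag(H))) + 1e-12)
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step)) break
    Xt <- t(X); Xt[free_dof] <- Xt[free_dof] + step; Xc <- t(Xt)
    resc <- max(abs(gvec(Xc)[free_dof]))
    if (resc < res) { X <- Xc; res <- resc } else break
  }
  list(X = X, residual = res, iterations = iters)
}

#' Solve a displacement-controlled gating trajectory
#'
#' Moves the prescribed nodes along their displacement path in
#' increments and equilibrates the free nodes at each increment.
#' Non-convergent increments are retried with up to 5 bisections of the
#' load step; if equilibrium still cannot be reached the trajectory is
#' truncated and flagged with the failing increment.
#'
#' @param mesh an `msclrod_mesh`.
#' @param connectors a `connector_set` (or `NULL` for a bare rod model).
#' @param bcs a `boundary_conditions` object.
#' @param tol residual force tolerance, pN; default
#'   `1e-6 * max(E * A)` over the rod elements (a characteristic
#'   elastic force).
#' @param max_iter Newton iteration cap per increment.
#' @param store_coords keep nodal coordinates for every increment
#'   (default `TRUE`; the final state is always kept).
#' @return an `equilibrium_trajectory`: per-increment pore diameter,
#'   rod element stresses (pN/A^2), connector gaps and forces, residual
#'   norms and iteration counts, plus the mesh and boundary conditions.
#' @export
solve_gating <- function(mesh, connectors, bcs, tol = NULL, max_iter = 60L,
                         store_coords = TRUE) {
  stopifnot(inherits(mesh, "msclrod_mesh"), inherits(bcs, "boundary_conditions"))
  conn_idx <- NULL
  if (!is.null(connectors) && nrow(connectors)) {
    conn_idx <- resolve_connectors(connectors, mesh)
    conn_idx$law <- connectors$law
  }
  if (is.null(tol)) {
    rod <- mesh$pairs$kind == "rod"
    char_force <- if (any(rod, na.rm = TRUE))
      max(mesh$pairs$E[rod] * mesh$pairs$area[rod], na.rm = TRUE)
    else max(mesh$pairs$k * mesh$pairs$L0, 1)
    tol <- 1e-6 * char_force
  }
  n <- nrow(mesh$X0)
  fixed_dof <- as.vector(vapply(bcs$fixed, function(i) .dof(i, 1:3),
                                integer(3)))
  # prescribed DOFs of pulled nodes: only the masked coordinates
  pull_dof <- integer(0); pull_delta <- numeric(0)
  if (length(bcs$pulled)) {
    for (d in 1:3) {
      sel <- bcs$dof_mask[, d]
      pull_dof <- c(pull_dof, .dof(bcs$pulled[sel], d))
      pull_delta <- c(pull_delta, bcs$targets[sel, d])
    }
  }
  free_dof <- setdiff(seq_len(3L * n), c(fixed_dof, pull_dof))
  x0vec <- as.vector(t(mesh$X0))
  rod_el <- which(mesh$pairs$kind == "rod")
  has_fiber <- nrow(mesh$bends) > 0 && any(mesh$bends$fiber > 0)

  snapshot <- function(X, t, eq) {
    d <- X[mesh$pairs$b[rod_el], , drop = FALSE] -
      X[mesh$pairs$a[rod_el], , drop = FALSE]
    l <- sqrt(rowSums(d^2))
    sigma <- mesh$pairs$E[rod_el] * (l - mesh$pairs$L0[rod_el]) /
      mesh$pairs$L0[rod_el]
    if (has_fiber) {
      # outer-fiber bending stress at interior nodes, added to the
      # membrane (axial) component: the combined axial stress a solid
      # rod reports
      bt <- .bend_terms(mesh$bends, X)
      sb <- mesh$bends$fiber * sqrt(pmax(1 - bt$cth^2, 0))
      node_fb <- numeric(n)
      for (q in seq_along(sb))
        node_fb[mesh$bends$j[q]] <- max(node_fb[mesh$bends$j[q]], sb[q])
      fib <- pmax(node_fb[mesh$pairs$a[rod_el]],
                  node_fb[mesh$pairs$b[rod_el]])
      sigma <- sign(sigma) * (abs(sigma) + fib)
    }
    pore <- if (length(mesh$window_nodes))
      2 * min(.radial_distance(X[mesh$window_nodes, , drop = FALSE],
                               mesh$center, mesh$axis)) else NA_real_
    conn <- NULL
    if (!is.null(conn_idx)) {
      dc <- X[conn_idx$node_b, , drop = FALSE] -
        X[conn_idx$node_a, , drop = FALSE]
      r <- sqrt(rowSums(dc^2))
      f <- vapply(seq_along(r), function(j)
        connector_force(conn_idx$law[[j]], r[j]), 0)
      conn <- list(r = r, f = f)
    }
    list(t = t, pore = pore, stress = sigma, connectors = conn,
         residual = eq$residual, iterations = eq$iterations,
         converged = eq$converged,
         X = if (store_coords) X else NULL)
  }

  X <- mesh$X0
  eq0 <- .equilibrate(mesh, conn_idx, X, free_dof, tol, max_iter)
  X <- eq0$X
  steps <- vector("list", bcs$increments + 1L)
  steps[[1L]] <- snapshot(X, 0, eq0)
  truncated_at <- NA_integer_

  t_prev <- 0
  for (inc in seq_len(bcs$increments)) {
    t_target <- inc / bcs$increments
    advance <- function(t0, t1, X, depth) {
      Xt <- t(X)
      Xt[pull_dof] <- x0vec[pull_dof] + t1 * pull_delta
      Xt <- t(Xt)
      eq <- .equilibrate(mesh, conn_idx, Xt, free_dof, tol, max_iter)
      if (eq$converged || depth >= 5L) return(eq)
      tm <- (t0 + t1) / 2
      mid <- advance(t0, tm, X, depth + 1L)
      if (!mid$converged) return(mid)
      advance(tm, t1, mid$X, depth + 1L)
    }
    eq <- advance(t_prev, t_target, X, 0L)
    X <- eq$X
    steps[[inc + 1L]] <- snapshot(X, t_target, eq)
    t_prev <- t_target
    if (!eq$converged) { truncated_at <- inc; break }
  }
  steps <- steps[!vapply(steps, is.null, TRUE)]
  structure(
    list(steps = steps, mesh = mesh, connectors = connectors, bcs = bcs,
         tol = tol, truncated_at = truncated_at,
         final_X = X),
    class = "equilibrium_trajectory")
}

#' @export
print.equilibrium_trajectory <- function(x, ...) {
  p <- traj_pore(x)
  cat(sprintf(
    "<equilibrium_trajectory> %d increments; pore %.2f -> %.2f A%s\n",
    length(x$steps) - 1L, p[1], p[length(p)],
    if (!is.na(x$truncated_at))
      paste0(" [TRUNCATED at increment ", x$truncated_at, "]") else ""))
  invisible(x)
}

#' Per-increment pore diameter of a trajectory
#' @param traj an `equilibrium_trajectory`.
#' @return numeric vector (length increments + 1).
#' @export
traj_pore <- function(traj) vapply(traj$steps, `[[`, 0, "pore")

#' Per-increment mean absolute axial stress over the TM1 elements
#' @param traj an `equilibrium_trajectory`.
#' @return numeric vector, pN/A^2.
#' @export
traj_tm1_stress <- function(traj) {
  rod_el <- which(traj$mesh$pairs$kind == "rod")
  tm1 <- traj$mesh$pairs$helix[rod_el] == "TM1"
  vapply(traj$steps, function(s) mean(abs(s$stress[tm1])), 0)
}

#' Pore-opening and TM1 stress metrics of a trajectory
#'
#' The channel counts as opened when the final pore diameter reaches
#' `open_threshold` (default 25 A). The threshold stress is the largest
#' mean absolute axial TM1 stress experienced over the whole trajectory
#' (after which the pore expands towards the open state); the
#' open-state stress is the same average at the final increment. Both
#' are absent (`NA`) when the channel did not open, as are the
#' corresponding table entries. The onset increment -- the first at
#' which the pore exceeds the closed diameter plus `onset_frac` of the
#' closed-to-open gain -- is reported alongside.
#'
#' @param traj an `equilibrium_trajectory`.
#' @param open_threshold opened-flag diameter, A.
#' @param onset_frac fraction of the closed-to-open diameter gain
#'   defining "significant expansion" (default 0.25).
#' @param open_diameter nominal fully open diameter, A (default 28).
#' @return list with `opened`, `pore_closed`, `pore_final`,
#'   `threshold_MPa`, `open_state_MPa`, `onset_increment`,
#'   `helix_max_MPa` (named vector over helices).
#' @export
tm1_stress_metrics <- function(traj, open_threshold = 25, onset_frac = 0.25,
                               open_diameter = 28) {
  stopifnot(inherits(traj, "equilibrium_trajectory"))
  if (length(traj$steps) < 2L)
    stop("tm1_stress_metrics: trajectory needs at least 2 increments")
  pore <- traj_pore(traj)
  s_tm1 <- traj_tm1_stress(traj)
  closed <- pore[1L]
  final <- pore[length(pore)]
  opened <- is.finite(final) && final >= open_threshold
  onset_level <- closed + onset_frac * (open_diameter - closed)
  onset <- which(pore > onset_level)[1L]

  rod_el <- which(traj$mesh$pairs$kind == "rod")
  hel <- traj$mesh$pairs$helix[rod_el]
  hmax <- vapply(c("N", "TM1", "TM2", "C"), function(h) {
    if (!any(hel == h)) return(0)
    max(vapply(traj$steps, function(s) max(abs(s$stress[hel == h])), 0))
  }, 0)
  list(
    opened = opened,
    pore_closed = closed,
    pore_final = final,
    threshold_MPa = if (opened) pN_A2_to_MPa(max(s_tm1)) else NA_real_,
    open_state_MPa = if (opened)
      pN_A2_to_MPa(s_tm1[length(s_tm1)]) else NA_real_,
    onset_increment = if (length(onset) && !is.na(onset))
      onset - 1L else NA_integer_,
    helix_max_MPa = pN_A2_to_MPa(hmax))
}

#' @rdname pore_diameter
#' @param state optional n x 3 coordinate matrix for a deformed state
#'   of the mesh (defaults to the rest coordinates).
#' @export
pore_diameter.msclrod_mesh <- function(x, state = NULL, ...) {
  X <- if (is.null(state)) x$X0 else state
  if (!length(x$window_nodes))
    stop("pore_diameter: mesh has no constriction window nodes")
  2 * min(.radial_distance(X[x$window_nodes, , drop = FALSE],
                           x$center, x$axis))
}
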