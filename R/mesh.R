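#' Discretize a channel geometry into a rod-and-connector mesh
#'
#' Every helix centerline becomes a chain of two-node elastic segments
#' carrying axial stiffness `E * A / L` (A = pi r^2); transverse rod
#' stiffness comes from discrete bending springs at interior nodes
#' (stiffness `E * I / l`, I = pi r^4 / 4, straight rest curvature).
#' The N-terminal rod is tied to the cytoplasmic end of TM1 (and TM2 to
#' the C-terminal bundle) by short link springs plus "brace" springs
#' across the junction that transmit bending moments. TM1 nodes are
#' placed so that every pore-lock anchor residue (16, 19, 20, 22, 23,
#' 26) coincides with a mesh node.
#'
#' @param geometry a `channel_geometry`.
#' @param specs named list of [helix_spec()]s (default from
#'   [synthetic_defaults()]).
#' @param elements_per_helix segments per helix rod (>= 7 so the TM1
#'   anchor residues can be resolved; default 8).
#' @param defaults a [synthetic_defaults()] object.
#' @return an `msclrod_mesh`: list with node coordinates `X0`,
#'   `node_meta` (subunit, helix, arclength, residue), `pairs` (axial
#'   springs: elements, links, braces), `bends` (bending triples),
#'   `anchor_lookup`, `window_nodes` and role node sets.
#' @export
#' @examples
#' mesh <- discretize(gen_geometry("WT", "closed"))
#' nrow(mesh$X0) # 5 subunits x 4 helices x 9 nodes = 180
discretize <- function(geometry, specs = NULL, elements_per_helix = 8L,
                       defaults = synthetic_defaults()) {
  stopifnot(inherits(geometry, "channel_geometry"))
  if (is.null(specs)) specs <- defaults$helices
  e <- as.integer(elements_per_helix)
  if (e < 7L)
    stop("discretize: elements_per_helix must be >= 7 to resolve the ",
         "pore-lock anchor residues on TM1")
  gp <- geometry$params
  anchors <- sort(unique(c(defaults$belts$res_a, defaults$belts$res_b)))

  # node arclength positions for one helix
  node_s <- function(helix, poly) {
    L <- max(attr(poly, "arclength"))
    if (helix == "TM1") {
      req <- sort(unique(c(0, tm1_arclength(anchors, gp), L)))
      if (length(req) > e + 1L)
        stop("discretize: elements_per_helix too small for anchor residues")
      s <- req
      while (length(s) < e + 1L) { # split the largest gap
        gaps <- diff(s)
        i <- which.max(gaps)
        s <- sort(c(s, s[i] + gaps[i] / 2))
      }
      s
    } else {
      seq(0, L, length.out = e + 1L)
    }
  }

  interp_poly <- function(poly, s) {
    sa <- attr(poly, "arclength")
    cbind(stats::approx(sa, poly[, 1], s)$y,
          stats::approx(sa, poly[, 2], s)$y,
          stats::approx(sa, poly[, 3], s)$y)
  }

  helix_order <- c("N", "TM1", "TM2", "C")
  nodes <- list(); meta <- list()
  pairs <- list(); bends <- list()
  offset <- 0L
  idx_of <- list() # [[subunit]][[helix]] -> node indices
  for (k in 0:4) {
    idx_of[[k + 1L]] <- list()
    for (h in helix_order) {
      poly <- geometry$subunits[[k + 1L]][[h]]
      sp <- specs[[h]]
      s <- node_s(h, poly)
      P <- interp_poly(poly, s)
      n_h <- nrow(P)
      idx <- offset + seq_len(n_h)
      idx_of[[k + 1L]][[h]] <- idx
      nodes[[length(nodes) + 1L]] <- P
      res <- if (h == "TM1") {
        rr <- range(gp$tm1_residues)
        rr[1] + s / sp$length * diff(rr)
      } else rep(NA_real_, n_h)
      meta[[length(meta) + 1L]] <- data.frame(
        subunit = k, helix = h, s = s, residue = res)
      A <- rod_area(sp)
      L0 <- diff(s)
      pairs[[length(pairs) + 1L]] <- data.frame(
        a = idx[-n_h], b = idx[-1L], k = sp$E * A / L0, L0 = L0,
        kind = "rod", helix = h, subunit = k, E = sp$E, area = A)
      if (n_h > 2L) {
        lbar <- (L0[-length(L0)] + L0[-1L]) / 2
        I <- pi * sp$radius^4 / 4
        bends[[length(bends) + 1L]] <- data.frame(
          i = idx[1:(n_h - 2L)], j = idx[2:(n_h - 1L)], k = idx[3:n_h],
          kb = sp$E * I / lbar,
          # outer-fiber bending stress per unit sin(theta):
          # sigma_b = M r / I with M = kb sin(theta)
          fiber = sp$E * sp$radius / lbar)
      }
      offset <- offset + n_h
    }
  }
  X0 <- do.call(rbind, nodes)
  meta <- do.call(rbind, meta)
  pairs <- do.call(rbind, pairs)
  bends <- do.call(rbind, bends)

  # junction links and braces
  link <- function(a, b, E, area, kind) {
    L0 <- sqrt(sum((X0[b, ] - X0[a, ])^2))
    data.frame(a = a, b = b, k = E * area / L0, L0 = L0, kind = kind,
               helix = NA_character_, subunit = NA_integer_,
               E = NA_real_, area = NA_real_)
  }
  jn <- list()
  for (k in 0:4) {
    io <- idx_of[[k + 1L]]
    nE <- specs$N$E; nA <- rod_area(specs$N)
    res15 <- io$TM1[1L]
    res16 <- io$TM1[2L]
    jn[[length(jn) + 1L]] <- link(io$N[1L], res15, nE, nA, "link")
    jn[[length(jn) + 1L]] <- link(io$N[2L], res15, nE, nA, "brace")
    jn[[length(jn) + 1L]] <- link(io$N[1L], res16, nE, nA, "brace")
    cE <- specs$C$E; cA <- rod_area(specs$C)
    jn[[length(jn) + 1L]] <- link(io$TM2[length(io$TM2)], io$C[1L],
                                  cE, cA, "link")
  }
  pairs <- rbind(pairs, do.call(rbind, jn))

  # lookups
  tm1 <- which(meta$helix == "TM1")
  int_res <- round(meta$residue[tm1])
  is_int <- abs(meta$residue[tm1] - int_res) < 1e-9
  anchor_lookup <- stats::setNames(
    tm1[is_int], paste(meta$subunit[tm1][is_int], int_res[is_int]))
  win <- gp$window
  window_nodes <- tm1[meta$residue[tm1] >= min(win) - 1e-9 &
                        meta$residue[tm1] <= max(win) + 1e-9]

  roles <- list(
    tm1_top = vapply(1:5, function(k) {
      i <- idx_of[[k]]$TM1; i[length(i)] }, 0L),
    tm2_top = vapply(1:5, function(k) idx_of[[k]]$TM2[1L], 0L),
    c_end = vapply(1:5, function(k) {
      i <- idx_of[[k]]$C; i[length(i)] }, 0L),
    n_outer = as.integer(unlist(lapply(1:5, function(k) {
      i <- idx_of[[k]]$N; i[c(length(i) - 1L, length(i))] }))),
    tm1_bottom = as.integer(unlist(lapply(1:5, function(k)
      idx_of[[k]]$TM1[1:2]))))

  structure(
    list(X0 = X0, node_meta = meta, pairs = pairs, bends = bends,
         anchor_lookup = anchor_lookup, window_nodes = window_nodes,
         roles = roles, idx_of = idx_of,
         axis = geometry$axis, center = geometry$center,
         elements_per_helix = e, specs = specs),
    class = "msclrod_mesh")
}

#' @export
print.msclrod_mesh <- function(x, ...) {
  cat(sprintf("<msclrod_mesh> %d nodes, %d axial springs (%d rod), %d bending triples\n",
              nrow(x$X0), nrow(x$pairs), sum(x$pairs$kind == "rod"),
              nrow(x$bends)))
  invisible(x)
}

#' Build a small mesh from explicit parts (for tests and custom models)
#'
#' Low-level constructor accepting node coordinates plus optional axial
#' spring and bending tables in the same layout [discretize()] emits.
#'
#' @param X0 n x 3 coordinate matrix.
#' @param pairs data.frame with columns `a`, `b`, `k`, `L0` (and
#'   optionally `kind`, `helix`, `subunit`, `E`, `area`).
#' @param bends data.frame with columns `i`, `j`, `k`, `kb`, or `NULL`.
#' @param anchor_lookup optional named node-index vector for connector
#'   resolution (names `"subunit residue"`).
#' @param window_nodes optional node indices for pore measurement.
#' @return an `msclrod_mesh`.
#' @export
mesh_from_parts <- function(X0, pairs = NULL, bends = NULL,
                            anchor_lookup = integer(), window_nodes = integer()) {
  X0 <- as.matrix(X0)
  stopifnot(ncol(X0) == 3)
  if (is.null(pairs))
    pairs <- data.frame(a = integer(), b = integer(), k = numeric(),
                        L0 = numeric())
  for (cn in c("kind", "helix")) if (is.null(pairs[[cn]]))
    pairs[[cn]] <- rep(if (cn == "kind") "rod" else NA_character_,
                       nrow(pairs))
  for (cn in c("subunit", "E", "area")) if (is.null(pairs[[cn]]))
    pairs[[cn]] <- rep(NA_real_, nrow(pairs))
  if (is.null(bends))
    bends <- data.frame(i = integer(), j = integer(), k = integer(),
                        kb = numeric())
  if (is.null(bends$fiber)) bends$fiber <- rep(0, nrow(bends))
  structure(list(X0 = X0, node_meta = NULL, pairs = pairs, bends = bends,
                 anchor_lookup = anchor_lookup, window_nodes = window_nodes,
                 roles = list(), idx_of = NULL,
                 axis = c(0, 0, 1), center = c(0, 0, 0),
                 elements_per_helix = NA_integer_, specs = NULL),
            class = "msclrod_mesh")
}

#' Displacement-controlled boundary conditions
#'
#' Fixed nodes are anchored at their rest position; pulled nodes follow
#' a linear path from rest to `targets` over `increments` equal steps.
#' A per-node coordinate mask restricts which components are prescribed
#' (e.g. `c(FALSE, FALSE, TRUE)` pulls along the channel axis only,
#' leaving the node free to move laterally). The pulled and fixed sets
#' must be disjoint.
#'
#' @param fixed node indices held at their initial position.
#' @param pulled node indices with prescribed displacement.
#' @param targets length(pulled) x 3 matrix of total displacements (A).
#' @param increments number of displacement increments (>= 1).
#' @param dof_mask length(pulled) x 3 logical matrix: which coordinates
#'   of each pulled node are prescribed (default: all three).
#' @return a `boundary_conditions` object.
#' @export
boundary_conditions <- function(fixed, pulled, targets, increments = 30L,
                                dof_mask = NULL) {
  fixed <- as.integer(fixed); pulled <- as.integer(pulled)
  targets <- matrix(as.numeric(targets), nrow = length(pulled), ncol = 3)
  if (is.null(dof_mask)) dof_mask <- matrix(TRUE, length(pulled), 3)
  dof_mask <- matrix(as.logical(dof_mask), nrow = length(pulled), ncol = 3)
  if (length(intersect(fixed, pulled)))
    stop("boundary_conditions: pulled and fixed sets must be disjoint")
  if (increments < 1L) stop("boundary_conditions: increments must be >= 1")
  structure(list(fixed = fixed, pulled = pulled, targets = targets,
                 increments = as.integer(increments), dof_mask = dof_mask),
            class = "boundary_conditions")
}

#' Gating boundary conditions for the pentamer mesh
#'
#' Builds the displacement protocol that takes the pulled nodes from
#' their initial closed positions to their final open positions (taken
#' from the open-target geometry discretized on the same node layout).
#' Pulled nodes are the outer two N-terminus nodes of each subunit --
#' the handle a cytoplasmic bead or nanoparticle grabs -- prescribed on
#' their full three-dimensional path. With `pull = "n+tm1"` the bottom
#' two TM1 nodes (residues 15-16) are additionally pulled, but along
#' the channel axis only (the pull direction): a bead cannot steer the
#' helix laterally, so the radial motion of TM1 remains an outcome of
#' the force balance rather than an imposed displacement. Fixed
#' anchors: the periplasmic top nodes of TM1 and TM2 and the far end of
#' the C-terminal bundle.
#'
#' @param mesh closed-state mesh from [discretize()].
#' @param open_mesh open-target mesh (same discretization settings).
#' @param pull `"n"` (N-terminus only) or `"n+tm1"`.
#' @param increments number of displacement increments.
#' @return a `boundary_conditions` object.
#' @export
gating_bcs <- function(mesh, open_mesh, pull = c("n", "n+tm1"),
                       increments = 30L) {
  pull <- match.arg(pull)
  stopifnot(inherits(mesh, "msclrod_mesh"), inherits(open_mesh, "msclrod_mesh"),
            nrow(mesh$X0) == nrow(open_mesh$X0))
  fixed <- c(mesh$roles$tm1_top, mesh$roles$tm2_top, mesh$roles$c_end)
  pulled <- mesh$roles$n_outer
  mask <- matrix(TRUE, length(pulled), 3)
  if (pull == "n+tm1") {
    tb <- mesh$roles$tm1_bottom
    pulled <- c(pulled, tb)
    mask <- rbind(mask,
                  matrix(rep(c(FALSE, FALSE, TRUE), length(tb)),
                         ncol = 3, byrow = TRUE))
  }
  targets <- open_mesh$X0[pulled, , drop = FALSE] -
    mesh$X0[pulled, , drop = FALSE]
  boundary_conditions(fixed, pulled, targets, increments, dof_mask = mask)
}
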