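#' Idealized pentameric channel geometry
#'
#' A `channel_geometry` holds, for each of the 5 subunits, centerline
#' polylines for the four helix rods (N, TM1, TM2, C), a residue-to-
#' arclength map for the pore-lining TM1 helix (residues 15-48), and the
#' channel axis (+z through the origin by construction). Geometries are
#' exactly 5-fold symmetric.
#'
#' @name channel_geometry
NULL

#' Default geometry parameters
#'
#' Constants of the idealized pentamer: rod lengths, TM1 tilt, closed
#' constriction radii (4 A WT, 5.5 A G22N, giving backbone-to-backbone
#' pore diameters of 8 and 11 A), the 14 A open-target constriction
#' (28 A pore), the TM1 residue span 15-48 and constriction window
#' 19-26, and the axial elongation fraction of the open-target state.
#'
#' @return a named list of geometry parameters.
#' @export
geometry_params <- function() {
  list(
    tm1_residues = 15:48,
    tm1_length   = 47.33,
    n_length     = 18.65,
    tm2_length   = 42.51,
    c_length     = 36.06,
    tilt_deg     = 25,          # TM1 tilt from the channel axis, closed state
    window       = 19:26,       # constriction window residues on TM1
    r_constrict  = c(WT = 4.0, G22N = 5.5, open = 14.0), # radii, A
    open_elongation = 0.08,     # TM1 arclength stretch in the open target
    n_gap        = 2.0,         # radial gap bridged by the N-TM1 link, A
    n_residues   = 1:14,
    tm2_offset   = 5.0,         # TM2 top radius offset beyond TM1 top, A
    tm2_tilt_deg = 10,
    tm2_residues = 70:100,
    c_radius     = 7.0,
    c_top_z      = -4.0,
    c_residues   = 105:125
  )
}

#' Arclength of a TM1 residue along the rod
#'
#' Residue `i` sits at fraction `(i - 15) / 33` of the TM1 rod length
#' (linear map over the residue span 15-48).
#'
#' @param residue residue number(s) in 15..48.
#' @param params geometry parameters.
#' @return arclength(s) from the cytoplasmic end, angstrom.
#' @export
tm1_arclength <- function(residue, params = geometry_params()) {
  rr <- range(params$tm1_residues)
  if (any(residue < rr[1] | residue > rr[2]))
    stop("tm1_arclength: residue outside the TM1 span ", rr[1], "-", rr[2])
  (residue - rr[1]) / diff(rr) * params$tm1_length
}

# polyline helper: matrix of points with arclength + residue attributes
.polyline <- function(coords, arclength, residues) {
  structure(coords, arclength = arclength, residues = residues)
}

# TM1 centerline in the (radial, z) half-plane of one subunit.
# Closed: straight rod tilted by tilt_deg, constriction radius at res 19.
# Open target: rod swung about its (fixed) periplasmic top node and
# stretched by (1 + open_elongation) so that the window constriction
# sits at the open radius.
.tm1_profile <- function(params, r_c, open = FALSE) {
  th <- params$tilt_deg * pi / 180
  res <- params$tm1_residues
  s <- tm1_arclength(res, params)
  L <- params$tm1_length
  s19 <- tm1_arclength(min(params$window), params)
  rho_closed <- r_c + (s - s19) * sin(th)
  z_closed <- s * cos(th)
  if (!open) return(list(rho = rho_closed, z = z_closed, s = s, res = res))
  rho_top <- r_c + (L - s19) * sin(th)
  z_top <- L * cos(th)
  Dk <- (L - s) * (1 + params$open_elongation)
  sw <- res %in% params$window
  f <- function(gam) min(rho_top + Dk[sw] * sin(gam)) - params$r_constrict[["open"]]
  gam <- stats::uniroot(f, c(-th, pi / 2 - 1e-6), tol = 1e-13)$root
  list(rho = rho_top + Dk * sin(gam), z = z_top - Dk * cos(gam), s = s,
       res = res, gamma = gam)
}

.cyl_to_xyz <- function(rho, phi, z) {
  cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
}

#' Generate an idealized closed or open-target pentamer geometry
#'
#' Builds the deterministic, exactly 5-fold symmetric rod-centerline
#' model of MscL. The closed WT constriction measures a pore diameter of
#' 8 A, the closed G22N 11 A, and the open target 28 A
#' (see [pore_diameter()]). The open target is obtained by swinging each
#' TM1 about its periplasmic end and stretching its arclength by the
#' configured elongation fraction; the N-terminal rod translates rigidly
#' with the cytoplasmic TM1 end (this is the "final open position" used
#' for displacement-controlled pulling).
#'
#' @param genotype `"WT"` or `"G22N"` (wider resting pore).
#' @param state `"closed"` or `"open-target"`.
#' @param params geometry parameters, see [geometry_params()].
#' @return a `channel_geometry`.
#' @export
#' @examples
#' g <- gen_geometry("WT", "closed")
#' pore_diameter(g) # 8
gen_geometry <- function(genotype = c("WT", "G22N"),
                         state = c("closed", "open-target"),
                         params = geometry_params()) {
  genotype <- match.arg(genotype)
  state <- match.arg(state)
  open <- state == "open-target"
  r_c <- params$r_constrict[[genotype]]

  tm1c <- .tm1_profile(params, r_c, open = FALSE)
  tm1 <- if (open) .tm1_profile(params, r_c, open = TRUE) else tm1c

  # N rod: horizontal, radial, at the cytoplasmic TM1 end level.
  n_np <- length(params$n_residues)
  rho15 <- tm1c$rho[1]
  n_rho_c <- seq(rho15 + params$n_gap,
                 rho15 + params$n_gap + params$n_length, length.out = n_np)
  n_z_c <- rep(tm1c$z[1], n_np)
  if (open) { # rigid translation with the res-15 end of TM1
    d_rho <- tm1$rho[1] - tm1c$rho[1]
    d_z <- tm1$z[1] - tm1c$z[1]
    n_rho <- n_rho_c + d_rho
    n_z <- n_z_c + d_z
  } else {
    n_rho <- n_rho_c
    n_z <- n_z_c
  }
  n_s <- seq(0, params$n_length, length.out = n_np)

  # TM2: outer helix, periplasmic top outward of the TM1 top.
  th2 <- params$tm2_tilt_deg * pi / 180
  tm2_np <- length(params$tm2_residues)
  s2 <- seq(0, params$tm2_length, length.out = tm2_np)
  rho_top1 <- tm1c$rho[length(tm1c$rho)]
  z_top1 <- tm1c$z[length(tm1c$z)]
  # ordered top (periplasmic) -> bottom (cytoplasmic)
  tm2_rho <- rho_top1 + params$tm2_offset + s2 * sin(th2)
  tm2_z <- z_top1 - s2 * cos(th2)

  # C-terminal bundle: vertical rod below the membrane, near the axis.
  c_np <- length(params$c_residues)
  s3 <- seq(0, params$c_length, length.out = c_np)
  c_rho <- rep(params$c_radius, c_np)
  c_z <- params$c_top_z - s3

  subunits <- vector("list", 5L)
  for (k in 0:4) {
    phi <- 2 * pi * k / 5
    subunits[[k + 1L]] <- list(
      N   = .polyline(.cyl_to_xyz(n_rho, phi, n_z), n_s, params$n_residues),
      TM1 = .polyline(.cyl_to_xyz(tm1$rho, phi, tm1$z), tm1$s, tm1$res),
      TM2 = .polyline(.cyl_to_xyz(tm2_rho, phi, tm2_z), s2, params$tm2_residues),
      C   = .polyline(.cyl_to_xyz(c_rho, phi, c_z), s3, params$c_residues)
    )
  }
  structure(
    list(genotype = genotype, state = state, params = params,
         axis = c(0, 0, 1), center = c(0, 0, 0), subunits = subunits),
    class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("<channel_geometry> %s %s; pore diameter %.3f A\n",
              x$genotype, x$state, pore_diameter(x)))
  invisible(x)
}

.radial_distance <- function(pts, center, axis) {
  v <- axis / sqrt(sum(axis^2))
  q <- sweep(pts, 2, center)
  t <- as.numeric(q %*% v)
  sqrt(pmax(rowSums(q^2) - t^2, 0))
}

#' Pore diameter at the TM1 constriction
#'
#' Twice the minimum radial distance to the channel axis over the
#' TM1 constriction-window nodes of all five subunits (backbone-to-
#' backbone convention). For a bare matrix of points the minimum is
#' taken over all rows.
#'
#' @param x a `channel_geometry`, or a numeric matrix of points (A).
#' @param window residue window on TM1 (default the geometry's own
#'   window, 19-26).
#' @param center a point on the channel axis.
#' @param axis axis direction.
#' @param ... passed to methods.
#' @return pore diameter in angstrom.
#' @export
pore_diameter <- function(x, ...) UseMethod("pore_diameter")

#' @rdname pore_diameter
#' @export
pore_diameter.channel_geometry <- function(x, window = NULL, ...) {
  if (is.null(window)) window <- x$params$window
  pts <- do.call(rbind, lapply(x$subunits, function(su) {
    res <- attr(su$TM1, "residues")
    su$TM1[res %in% window, , drop = FALSE]
  }))
  if (!nrow(pts)) stop("pore_diameter: empty constriction window")
  2 * min(.radial_distance(pts, x$center, x$axis))
}

#' @rdname pore_diameter
#' @export
pore_diameter.default <- function(x, center = c(0, 0, 0), axis = c(0, 0, 1),
                                  ...) {
  pts <- as.matrix(x)
  if (!nrow(pts)) stop("pore_diameter: no points")
  2 * min(.radial_distance(pts, center, axis))
}

#' Closed-state anchor separations of the pore-lock belts
#'
#' Distance between residue `res_a` on one subunit and `res_b` on the
#' next (counter-clockwise) subunit, measured on a geometry. These
#' separations define the belts' equilibrium distances in the synthetic
#' defaults, so the resting closed channel is an exact equilibrium of
#' the pore-lock.
#'
#' @param geometry a `channel_geometry`.
#' @param res_a,res_b TM1 residue numbers (vectors recycled together).
#' @return distances in angstrom.
#' @export
belt_anchor_distance <- function(geometry, res_a, res_b) {
  stopifnot(inherits(geometry, "channel_geometry"))
  su1 <- geometry$subunits[[1L]]$TM1
  su2 <- geometry$subunits[[2L]]$TM1
  res <- attr(su1, "residues")
  ia <- match(res_a, res)
  ib <- match(res_b, res)
  if (anyNA(ia) || anyNA(ib))
    stop("belt_anchor_distance: residue not on the TM1 polyline")
  sqrt(rowSums((su1[ia, , drop = FALSE] - su2[ib, , drop = FALSE])^2))
}
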