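#' Generalized Lennard-Jones force laws for pore-lock interactions
#'
#' A pairwise van der Waals interaction between pore-lining residues of
#' neighbouring TM1 helices is described by the force law
#' \deqn{F(r) = 12 A / r^m - 6 B / r^n}
#' (in kcal/mol/A, reported in pN; positive = repulsive), the negative
#' gradient of the 12-6 energy \eqn{E(r) = A/r^{12} - B/r^6} when
#' \eqn{(m, n) = (13, 7)}. Free exponents \eqn{m > n \ge 2} accommodate
#' belts whose simulated force curves deviate from the ideal 12-6 shape.
#'
#' @param A repulsive constant (> 0), kcal/mol * A^(m-1) scale.
#' @param B attractive constant (> 0).
#' @param m repulsive force exponent (default 13).
#' @param n attractive force exponent (default 7).
#' @param pair optional belt label, e.g. "V16-G22".
#' @param genotype optional genotype label ("WT" or "G22N").
#'
#' @return An object of class `force_law`.
#' @export
#' @examples
#' law <- force_law(A = 2, B = 4)
#' law_r_eq(law)       # 1
#' law_well_depth(law) # 2
force_law <- function(A, B, m = 13, n = 7, pair = NULL, genotype = NULL) {
  stopifnot(is.numeric(A), is.numeric(B), length(A) == 1L, length(B) == 1L)
  if (!is.finite(A) || !is.finite(B) || A <= 0 || B <= 0)
    stop("force_law: A and B must be finite and > 0 (got A=", A, ", B=", B, ")")
  if (!(m > n && n >= 2))
    stop("force_law: exponents must satisfy m > n >= 2 (got m=", m, ", n=", n, ")")
  structure(
    list(A = A, B = B, m = m, n = n,
         pair = pair, genotype = genotype),
    class = "force_law")
}

#' @export
print.force_law <- function(x, ...) {
  cat(sprintf("<force_law%s%s> A=%.6g B=%.6g m=%g n=%g",
              if (is.null(x$pair)) "" else paste0(" ", x$pair),
              if (is.null(x$genotype)) "" else paste0(" [", x$genotype, "]"),
              x$A, x$B, x$m, x$n))
  if (is_standard_lj(x))
    cat(sprintf("  (r_eq=%.4g A, depth=%.4g kcal/mol)",
                law_r_eq(x), law_well_depth(x)))
  cat("\n")
  invisible(x)
}

#' Is a force law in the standard 12-6 form?
#'
#' Energy is defined only for `(m, n) = (13, 7)` force exponents.
#' @param law a `force_law`.
#' @return logical.
#' @export
is_standard_lj <- function(law) law$m == 13 && law$n == 7

.check_r <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    stop("distance r must be finite and > 0")
  r
}

#' Lennard-Jones interaction energy
#'
#' `E(r) = A/r^12 - B/r^6` in kcal/mol. Defined only for standard
#' `(m, n) = (13, 7)` laws; generalized-exponent laws have a tabulated
#' force but no closed 12-6 energy and are rejected explicitly.
#'
#' @param law a `force_law` with `m = 13`, `n = 7`.
#' @param r distance(s) in angstrom, > 0.
#' @return energy in kcal/mol.
#' @export
#' @examples
#' lj_energy(force_law(1, 2), 1) # -1
lj_energy <- function(law, r) {
  stopifnot(inherits(law, "force_law"))
  if (!is_standard_lj(law))
    stop("lj_energy: energy is defined only for (m, n) = (13, 7); ",
         "this law has m=", law$m, ", n=", law$n)
  .check_r(r)
  law$A / r^12 - law$B / r^6
}

#' Lennard-Jones interaction force
#'
#' `F(r) = 12 A / r^m - 6 B / r^n` evaluated in kcal/mol/A and converted
#' to pN (positive = repulsive). For standard exponents this is exactly
#' `-dE/dr` of [lj_energy()].
#'
#' @inheritParams lj_energy
#' @param law a `force_law` (any admissible exponents).
#' @return force in pN.
#' @export
#' @examples
#' lj_force(force_law(1, 2), 1) # 0: r_eq = (2A/B)^(1/6) = 1
lj_force <- function(law, r) {
  stopifnot(inherits(law, "force_law"))
  .check_r(r)
  kcalmol_per_A_to_pN(12 * law$A / r^law$m - 6 * law$B / r^law$n)
}

#' Equilibrium distance of a standard 12-6 law
#'
#' `r_eq = (2A/B)^(1/6)`, the zero-force separation.
#' @param law a standard `force_law`.
#' @return distance in angstrom.
#' @export
law_r_eq <- function(law) {
  stopifnot(inherits(law, "force_law"))
  if (!is_standard_lj(law))
    stop("law_r_eq: closed form defined only for (m, n) = (13, 7)")
  (2 * law$A / law$B)^(1 / 6)
}

#' Well depth of a standard 12-6 law
#'
#' `depth = B^2 / (4A)` in kcal/mol (the magnitude of the energy minimum).
#' @param law a standard `force_law`.
#' @return depth in kcal/mol.
#' @export
law_well_depth <- function(law) {
  stopifnot(inherits(law, "force_law"))
  if (!is_standard_lj(law))
    stop("law_well_depth: closed form defined only for (m, n) = (13, 7)")
  law$B^2 / (4 * law$A)
}

#' Build a standard 12-6 law from well depth and equilibrium distance
#'
#' Inverse of [law_well_depth()] / [law_r_eq()]:
#' `A = depth * r_eq^12`, `B = 2 * depth * r_eq^6`.
#'
#' @param depth well depth in kcal/mol (> 0).
#' @param r_eq equilibrium distance in angstrom (> 0).
#' @inheritParams force_law
#' @return a `force_law`.
#' @export
law_from_well <- function(depth, r_eq, pair = NULL, genotype = NULL) {
  stopifnot(depth > 0, r_eq > 0)
  force_law(A = depth * r_eq^12, B = 2 * depth * r_eq^6,
            pair = pair, genotype = genotype)
}

#' Uniformly weaken an interaction
#'
#' Scales both `A` and `B` by `(1 - rho)`, so the well depth scales by
#' `(1 - rho)` while the equilibrium distance is unchanged. `rho = 1`
#' yields an identically zero force; such fully deleted laws are kept as
#' a degenerate `force_law` with a `zero` flag.
#'
#' @param law a `force_law`.
#' @param rho reduction fraction in `[0, 1]`.
#' @return a `force_law` (with attribute `zero = TRUE` when `rho = 1`).
#' @export
#' @examples
#' law <- law_from_well(2, 6)
#' law_well_depth(apply_reduction(law, 0.5)) # 1
apply_reduction <- function(law, rho) {
  stopifnot(inherits(law, "force_law"))
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      rho < 0 || rho > 1)
    stop("apply_reduction: rho must be a single value in [0, 1] (got ",
         format(rho), ")")
  if (rho == 1) {
    out <- law
    out$A <- 0
    out$B <- 0
    class(out) <- c("zero_force_law", "force_law")
    return(out)
  }
  out <- law
  out$A <- law$A * (1 - rho)
  out$B <- law$B * (1 - rho)
  out
}

#' @export
print.zero_force_law <- function(x, ...) {
  cat("<force_law> fully reduced (zero force)\n")
  invisible(x)
}

#' Connector force with a short-range linear continuation
#'
#' Inside the solver the `r^-m` repulsion is linearized below a floor
#' distance (default `0.75 * r_eq` for standard laws) so that Newton
#' iterates cannot overflow the power law; the continuation is tangent
#' (force and slope continuous) at the floor.
#'
#' @param law a `force_law` (possibly zero).
#' @param r distances in angstrom.
#' @param r_floor floor distance; `NULL` picks `0.75 * r_eq` for standard
#'   laws and the force zero-crossing times 0.75 otherwise.
#' @return force in pN (positive = repulsive).
#' @keywords internal
connector_force <- function(law, r, r_floor = NULL) {
  if (inherits(law, "zero_force_law")) return(rep(0, length(r)))
  if (is.null(r_floor)) r_floor <- 0.75 * law_r_eq_any(law)
  out <- numeric(length(r))
  lo <- r < r_floor
  if (any(!lo)) out[!lo] <- lj_force(law, r[!lo])
  if (any(lo)) {
    f0 <- lj_force(law, r_floor)
    # dF/dr at the floor, pN/A
    slope <- kcalmol_per_A_to_pN(
      -12 * law$m * law$A / r_floor^(law$m + 1) +
        6 * law$n * law$B / r_floor^(law$n + 1))
    out[lo] <- f0 + slope * (r[lo] - r_floor)
  }
  out
}

#' Force slope dF/dr of a connector (with floor continuation)
#' @keywords internal
connector_force_slope <- function(law, r, r_floor = NULL) {
  if (inherits(law, "zero_force_law")) return(rep(0, length(r)))
  if (is.null(r_floor)) r_floor <- 0.75 * law_r_eq_any(law)
  r_eff <- pmax(r, r_floor)
  kcalmol_per_A_to_pN(
    -12 * law$m * law$A / r_eff^(law$m + 1) +
      6 * law$n * law$B / r_eff^(law$n + 1))
}

#' Zero-force separation for any admissible exponents
#'
#' Solves `12 A / r^m = 6 B / r^n`, i.e. `r = (2A/B)^(1/(m-n))`.
#' @param law a `force_law`.
#' @return distance in angstrom.
#' @export
law_r_eq_any <- function(law) {
  if (inherits(law, "zero_force_law"))
    stop("law_r_eq_any: zero law has no equilibrium distance")
  (2 * law$A / law$B)^(1 / (law$m - law$n))
}
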