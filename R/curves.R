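#' Sampled pairwise interaction curves
#'
#' An `interaction_curve` holds sampled energy and/or force versus
#' distance data for one residue-pair belt and genotype, either taken
#' from molecular-dynamics output (via [read_curve_file()]) or produced
#' by the synthetic generator [gen_interaction_curve()].
#'
#' @param distance strictly increasing positive distances, angstrom.
#' @param energy optional energies, kcal/mol.
#' @param force optional forces, pN (positive = repulsive). At least one
#'   of `energy`/`force` must be given.
#' @param pair belt label.
#' @param genotype genotype label.
#' @return an `interaction_curve`.
#' @export
interaction_curve <- function(distance, energy = NULL, force = NULL,
                              pair = NULL, genotype = NULL) {
  if (!is.numeric(distance) || length(distance) == 0L)
    stop("interaction_curve: distance must be a non-empty numeric vector")
  if (any(!is.finite(distance)) || any(distance <= 0))
    stop("interaction_curve: distances must be finite and > 0")
  if (is.unsorted(distance, strictly = TRUE))
    stop("interaction_curve: distances must be strictly increasing")
  if (is.null(energy) && is.null(force))
    stop("interaction_curve: at least one of energy/force is required")
  if (!is.null(energy) && length(energy) != length(distance))
    stop("interaction_curve: energy and distance lengths differ")
  if (!is.null(force) && length(force) != length(distance))
    stop("interaction_curve: force and distance lengths differ")
  if (!is.null(energy) && any(!is.finite(energy)))
    stop("interaction_curve: non-finite energy values")
  if (!is.null(force) && any(!is.finite(force)))
    stop("interaction_curve: non-finite force values")
  structure(
    list(distance = as.numeric(distance),
         energy = if (is.null(energy)) NULL else as.numeric(energy),
         force = if (is.null(force)) NULL else as.numeric(force),
         pair = pair, genotype = genotype),
    class = "interaction_curve")
}

#' @export
print.interaction_curve <- function(x, ...) {
  cat(sprintf("<interaction_curve%s%s> %d samples, r in [%.3g, %.3g] A; channels: %s\n",
              if (is.null(x$pair)) "" else paste0(" ", x$pair),
              if (is.null(x$genotype)) "" else paste0(" [", x$genotype, "]"),
              length(x$distance), min(x$distance), max(x$distance),
              paste(c("energy", "force")[
                c(!is.null(x$energy), !is.null(x$force))], collapse = "+")))
  invisible(x)
}

#' Derive forces from an energy-only curve by central differences
#'
#' `F = -dE/dr` (kcal/mol/A), converted to pN. One-sided differences are
#' used at the ends.
#'
#' @param curve an `interaction_curve` carrying energies.
#' @return the curve with a `force` channel added (existing forces kept).
#' @export
curve_force_from_energy <- function(curve) {
  stopifnot(inherits(curve, "interaction_curve"))
  if (is.null(curve$energy))
    stop("curve_force_from_energy: curve has no energy channel")
  if (!is.null(curve$force)) return(curve)
  r <- curve$distance
  e <- curve$energy
  k <- length(r)
  if (k < 3L) stop("curve_force_from_energy: need at least 3 samples")
  dEdr <- numeric(k)
  dEdr[1] <- (e[2] - e[1]) / (r[2] - r[1])
  dEdr[k] <- (e[k] - e[k - 1]) / (r[k] - r[k - 1])
  if (k > 2L) {
    i <- 2:(k - 1L)
    dEdr[i] <- (e[i + 1L] - e[i - 1L]) / (r[i + 1L] - r[i - 1L])
  }
  curve$force <- kcalmol_per_A_to_pN(-dEdr)
  curve
}

#' Fit a generalized Lennard-Jones force law to a sampled curve
#'
#' Least squares in force space. With fixed exponents `(m, n) = (13, 7)`
#' the model is linear in `(A, B)` and solved exactly; with free
#' exponents the profiled sum of squares `SSE(m, n)` (inner linear solve
#' for `A`, `B`) is minimized by Nelder-Mead from a multistart grid
#' `m in {11, 13, 15} x n in {5, 7, 9}`, ties broken toward `(13, 7)`.
#' Energy-only curves are first differentiated with
#' [curve_force_from_energy()].
#'
#' @param curve an `interaction_curve` with at least 6 samples.
#' @param fix_exponents if `TRUE` (default) fit only `(A, B)` at
#'   `(m, n) = (13, 7)`.
#' @return a `force_law` with attributes `sse` (pN^2), `converged`
#'   (logical) and `n_obs`.
#' @export
#' @examples
#' law0 <- force_law(3, 5)
#' r <- seq(0.9, 2.5, length.out = 40)
#' fit <- fit_force_law(interaction_curve(r, force = lj_force(law0, r)))
#' c(fit$A, fit$B) # ~ (3, 5)
fit_force_law <- function(curve, fix_exponents = TRUE) {
  stopifnot(inherits(curve, "interaction_curve"))
  if (is.null(curve$force)) curve <- curve_force_from_energy(curve)
  r <- curve$distance
  f <- curve$force
  if (length(r) < 6L)
    stop("fit_force_law: need at least 6 force samples (got ", length(r), ")")
  if (any(!is.finite(f))) stop("fit_force_law: non-finite force samples")

  c0 <- .KCALMOL_PER_A_IN_PN
  # profiled linear solve for (A, B) at given exponents; returns list
  prof <- function(m, n) {
    X <- cbind(12 * c0 / r^m, -6 * c0 / r^n)
    ab <- tryCatch(qr.coef(qr(X), f), error = function(e) c(NA_real_, NA_real_))
    if (any(!is.finite(ab)) || any(ab <= 0))
      return(list(ok = FALSE, sse = Inf, A = NA, B = NA))
    res <- f - X %*% ab
    list(ok = TRUE, sse = sum(res^2), A = ab[1], B = ab[2])
  }

  fixed <- prof(13, 7)
  if (!fixed$ok) {
    # fall back: positivity-constrained fit in log-parameters
    obj <- function(p) {
      A <- exp(p[1]); B <- exp(p[2])
      sum((f - (12 * c0 * A / r^13 - 6 * c0 * B / r^7))^2)
    }
    # crude scale guess from the attractive tail
    B0 <- max(abs(f)) * max(r)^7 / (6 * c0)
    op <- stats::optim(log(c(B0 * 2, B0)), obj, method = "Nelder-Mead",
                       control = list(maxit = 2000))
    fixed <- list(ok = op$convergence == 0, sse = op$value,
                  A = exp(op$par[1]), B = exp(op$par[2]))
  }

  if (fix_exponents) {
    law <- force_law(fixed$A, fixed$B, 13, 7,
                     pair = curve$pair, genotype = curve$genotype)
    attr(law, "sse") <- fixed$sse
    attr(law, "converged") <- isTRUE(fixed$ok)
    attr(law, "n_obs") <- length(r)
    return(law)
  }

  # free exponents: minimize profiled SSE over (m, n), multistart
  obj_mn <- function(p) {
    m <- p[1]; n <- p[2]
    if (!(m > n && n >= 2) || m > 30) return(1e30)
    prof(m, n)$sse
  }
  best <- list(sse = fixed$sse, m = 13, n = 7, A = fixed$A, B = fixed$B,
               ok = fixed$ok)
  for (m0 in c(11, 13, 15)) for (n0 in c(5, 7, 9)) {
    op <- stats::optim(c(m0, n0), obj_mn, method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-12))
    pr <- prof(op$par[1], op$par[2])
    if (pr$ok && pr$sse < best$sse * (1 - 1e-12)) {
      best <- list(sse = pr$sse, m = op$par[1], n = op$par[2],
                   A = pr$A, B = pr$B, ok = op$convergence == 0)
    }
  }
  law <- force_law(best$A, best$B, best$m, best$n,
                   pair = curve$pair, genotype = curve$genotype)
  attr(law, "sse") <- best$sse
  attr(law, "converged") <- isTRUE(best$ok)
  attr(law, "n_obs") <- length(r)
  law
}

#' Peak-to-peak interaction reduction between genotypes
#'
#' `100 * (depth_WT - depth_mut) / depth_WT`, where depth is the absolute
#' value of the sampled minimum of the curve (energy channel when both
#' carry energies, otherwise the force channel for both). The sampled
#' minimum is used directly, without interpolation. Negative values mean
#' the mutant well is deeper.
#'
#' @param wt wild-type `interaction_curve`.
#' @param mut mutant `interaction_curve`.
#' @return reduction percentage (numeric scalar).
#' @export
#' @examples
#' r <- seq(4, 15, length.out = 50)
#' law <- law_from_well(2, 6)
#' wt <- interaction_curve(r, energy = lj_energy(law, r))
#' mu <- interaction_curve(r, energy = 0.5 * lj_energy(law, r))
#' peak_to_peak_reduction(wt, mu) # 50
peak_to_peak_reduction <- function(wt, mut) {
  stopifnot(inherits(wt, "interaction_curve"),
            inherits(mut, "interaction_curve"))
  use_energy <- !is.null(wt$energy) && !is.null(mut$energy)
  if (!use_energy && (is.null(wt$force) || is.null(mut$force)))
    stop("peak_to_peak_reduction: curves must share a channel ",
         "(both energies or both forces)")
  dwt <- if (use_energy) abs(min(wt$energy)) else abs(min(wt$force))
  dmu <- if (use_energy) abs(min(mut$energy)) else abs(min(mut$force))
  if (dwt == 0)
    stop("peak_to_peak_reduction: WT curve has zero well depth")
  100 * (dwt - dmu) / dwt
}

#' Read an interaction curve from a delimited text file
#'
#' Expects a TSV/CSV header naming a `distance_A` column plus at least
#' one of `energy_kcal_mol` / `force_pN`. Units are taken from the
#' column names; no unit guessing is performed. Lines starting with `#`
#' are comments. Rows are sorted by distance; duplicate distances and
#' non-numeric cells are rejected with row-level diagnostics.
#'
#' @param path file path.
#' @param pair,genotype optional labels attached to the curve.
#' @return an `interaction_curve`.
#' @export
read_curve_file <- function(path, pair = NULL, genotype = NULL) {
  if (!file.exists(path)) stop("read_curve_file: no such file: ", path)
  first <- readLines(path, n = 50L)
  first <- first[!grepl("^\\s*#", first) & nzchar(first)]
  if (!length(first)) stop("read_curve_file: ", path, " is empty")
  sep <- if (grepl("\t", first[1])) "\t" else if (grepl(",", first[1])) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = TRUE)
  if (!"distance_A" %in% names(df))
    stop("read_curve_file: missing required column 'distance_A' in ", path)
  have_e <- "energy_kcal_mol" %in% names(df)
  have_f <- "force_pN" %in% names(df)
  if (!have_e && !have_f)
    stop("read_curve_file: need at least one of 'energy_kcal_mol'/'force_pN' in ",
         path)
  for (cn in intersect(c("distance_A", "energy_kcal_mol", "force_pN"), names(df))) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stop("read_curve_file: non-numeric cells in column '", cn, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  o <- order(df$distance_A)
  df <- df[o, , drop = FALSE]
  if (anyDuplicated(df$distance_A)) {
    dup <- which(duplicated(df$distance_A))
    stop("read_curve_file: duplicate distances at sorted row(s) ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  interaction_curve(df$distance_A,
                    energy = if (have_e) df$energy_kcal_mol else NULL,
                    force = if (have_f) df$force_pN else NULL,
                    pair = pair, genotype = genotype)
}

#' Write an interaction curve as TSV
#'
#' Columns `distance_A` plus whichever of `energy_kcal_mol`/`force_pN`
#' the curve carries; a `#` comment line records pair and genotype.
#'
#' @param curve an `interaction_curve`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve_file <- function(curve, path) {
  stopifnot(inherits(curve, "interaction_curve"))
  df <- data.frame(distance_A = curve$distance)
  if (!is.null(curve$energy)) df$energy_kcal_mol <- curve$energy
  if (!is.null(curve$force)) df$force_pN <- curve$force
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# interaction curve%s%s",
                     if (is.null(curve$pair)) "" else paste0(" pair=", curve$pair),
                     if (is.null(curve$genotype)) ""
                     else paste0(" genotype=", curve$genotype)), con)
  utils::write.table(format(df, digits = 12, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check force/energy consistency of a two-channel curve
#'
#' Verifies that the force channel equals `-dE/dr` (central differences,
#' converted to pN) within a relative tolerance on the force scale.
#'
#' @param curve a curve with both channels.
#' @param rel_tol relative tolerance (default 0.05; differentiation of
#'   sampled data is itself approximate).
#' @return `TRUE`/`FALSE` with attribute `max_rel_err`.
#' @export
validate_curve_consistency <- function(curve, rel_tol = 0.05) {
  stopifnot(inherits(curve, "interaction_curve"))
  if (is.null(curve$energy) || is.null(curve$force))
    stop("validate_curve_consistency: curve must carry both channels")
  fd <- curve_force_from_energy(
    interaction_curve(curve$distance, energy = curve$energy))$force
  k <- length(fd)
  if (k < 4L) stop("validate_curve_consistency: too few samples")
  i <- 2:(k - 1L) # interior points only: one-sided ends are first-order
  scale <- max(abs(curve$force))
  err <- max(abs(fd[i] - curve$force[i])) / scale
  out <- err <= rel_tol
  attr(out, "max_rel_err") <- err
  out
}

#' Serialize fitted force laws to JSON
#'
#' @param laws a single `force_law` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_laws_json <- function(laws, path) {
  if (inherits(laws, "force_law")) laws <- list(laws)
  rec <- lapply(laws, function(l) {
    list(pair = if (is.null(l$pair)) NA else l$pair,
         genotype = if (is.null(l$genotype)) NA else l$genotype,
         A = l$A, B = l$B, m = l$m, n = l$n,
         sse = if (is.null(attr(l, "sse"))) NA else attr(l, "sse"))
  })
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read force laws from JSON written by [write_laws_json()]
#' @param path input path.
#' @return list of `force_law` objects.
#' @export
read_laws_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(rec, function(x)
    force_law(x$A, x$B, x$m, x$n,
              pair = if (is.null(x$pair) || is.na(x$pair)) NULL else x$pair,
              genotype = if (is.null(x$genotype) || isTRUE(is.na(x$genotype)))
                NULL else x$genotype))
}
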