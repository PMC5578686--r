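#' The eleven in-silico gating scenarios
#'
#' Scenarios 1-5 pull the N-terminus only; 6-11 pull the N-terminus
#' plus the bottom of TM1. Each scenario combines a uniform reduction
#' of the pore-lock interaction strength, optional deletion of an
#' entire belt (the G26 deletion removes V23-G26, the V16 deletion
#' removes V16-G22), or -- for scenario 11 -- the per-belt G22N
#' strength scalings measured from the genotype comparison of the
#' interaction curves.
#'
#' @name scenarios
NULL

#' Construct the specification of one in-silico scenario
#'
#' @param id scenario number, 1-11.
#' @return a `scenario_spec`: list with `id`, `genotype`, `rho`
#'   (uniform reduction; `NA` for per-belt G22N scaling), `deletions`,
#'   `pull` (`"n"` or `"n+tm1"`).
#' @export
#' @examples
#' make_scenario(5)  # 98% reduction, no deletions, N-terminus only
#' make_scenario(8)  # 50% reduction, V16-G22 deleted, N + TM1
make_scenario <- function(id) {
  if (!is.numeric(id) || length(id) != 1L || !(id %in% 1:11))
    stop("make_scenario: id must be one of 1..11 (got ", format(id), ")")
  id <- as.integer(id)
  tab <- list(
    list(pull = "n",     rho = 0.00, del = "V23-G26", genotype = "WT"),
    list(pull = "n",     rho = 0.50, del = "V23-G26", genotype = "WT"),
    list(pull = "n",     rho = 0.80, del = "V23-G26", genotype = "WT"),
    list(pull = "n",     rho = 0.90, del = "V23-G26", genotype = "WT"),
    list(pull = "n",     rho = 0.98, del = character(), genotype = "WT"),
    list(pull = "n+tm1", rho = 0.00, del = character(), genotype = "WT"),
    list(pull = "n+tm1", rho = 0.50, del = character(), genotype = "WT"),
    list(pull = "n+tm1", rho = 0.50, del = "V16-G22", genotype = "WT"),
    list(pull = "n+tm1", rho = 0.50, del = "V23-G26", genotype = "WT"),
    list(pull = "n+tm1", rho = 0.75, del = character(), genotype = "WT"),
    list(pull = "n+tm1", rho = NA_real_, del = character(), genotype = "G22N"))
  s <- tab[[id]]
  structure(list(id = id, genotype = s$genotype, rho = s$rho,
                 deletions = s$del, pull = s$pull),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec %d> %s pull=%s %s%s\n", x$id, x$genotype,
              x$pull,
              if (is.na(x$rho)) "per-belt G22N scaling"
              else sprintf("reduction %.0f%%", 100 * x$rho),
              if (length(x$deletions))
                paste0(", deleted: ", paste(x$deletions, collapse = ", "))
              else ""))
  invisible(x)
}

#' Force laws of a scenario's pore-lock
#'
#' WT scenarios use the nominal per-belt laws under a uniform
#' reduction. The G22N scenario applies the full genotype modification
#' measured from the interaction curves: the per-belt peak-to-peak
#' strength reduction together with the equilibrium right-shift (the
#' shift leaves the mutant lock slightly pre-stressed at the closed
#' anchor separations, reproducing its wider, destabilized resting
#' pore). Set `g22n_shift = FALSE` for strength-only scaling.
#'
#' @param spec a `scenario_spec`.
#' @param defaults a [synthetic_defaults()] object.
#' @param g22n_shift apply the mutant equilibrium right-shift (default
#'   `TRUE`).
#' @return named list of `force_law` objects per remaining belt.
#' @keywords internal
scenario_laws <- function(spec, defaults = synthetic_defaults(),
                          g22n_shift = TRUE) {
  bt <- defaults$belts
  belts <- setdiff(bt$belt, spec$deletions)
  laws <- lapply(belts, function(b) {
    if (identical(spec$genotype, "G22N")) {
      belt_law(b, "G22N", defaults, shift = g22n_shift)
    } else {
      law <- belt_law(b, "WT", defaults)
      if (!is.na(spec$rho)) law <- apply_reduction(law, spec$rho)
      law
    }
  })
  stats::setNames(laws, belts)
}

#' Run one in-silico gating scenario
#'
#' Builds the closed geometry and pore-lock, applies the scenario's
#' reductions and deletions, solves the displacement-controlled gating
#' protocol to full actuation, and extracts pore and stress metrics.
#' Deterministic given fixed inputs.
#'
#' @param spec a `scenario_spec` from [make_scenario()], or a scenario
#'   id.
#' @param defaults a [synthetic_defaults()] object.
#' @param increments displacement increments (default 30).
#' @param elements_per_helix mesh resolution (default 8).
#' @param use_g22n_geometry start scenario-11 runs from the wider G22N
#'   resting geometry instead of the WT one (sensitivity option;
#'   default `FALSE`).
#' @param g22n_shift apply the G22N equilibrium right-shift to the
#'   mutant laws (default `TRUE`; see [scenario_laws()]).
#' @param keep_trajectory attach the full `equilibrium_trajectory`.
#' @param ... further arguments passed to [solve_gating()].
#' @return a `scenario_result`: list with `id`, `pore_closed`,
#'   `pore_final` (A), `opened`, `threshold_MPa`, `open_state_MPa`
#'   (`NA` when not opened), `helix_max_MPa`, `feasibility` (per-helix
#'   verdicts), `converged`, and optionally `trajectory`.
#' @export
run_scenario <- function(spec, defaults = synthetic_defaults(),
                         increments = 30L, elements_per_helix = 8L,
                         use_g22n_geometry = FALSE, g22n_shift = TRUE,
                         keep_trajectory = FALSE, ...) {
  if (is.numeric(spec)) spec <- make_scenario(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  geno_geom <- if (use_g22n_geometry && identical(spec$genotype, "G22N"))
    "G22N" else "WT"
  closed <- gen_geometry(geno_geom, "closed", defaults$geometry)
  open <- gen_geometry(geno_geom, "open-target", defaults$geometry)
  mesh <- discretize(closed, defaults$helices, elements_per_helix, defaults)
  omesh <- discretize(open, defaults$helices, elements_per_helix, defaults)
  laws <- scenario_laws(spec, defaults, g22n_shift = g22n_shift)
  conn <- build_porelock(closed, laws = laws, deletions = spec$deletions,
                         rho = 0, defaults = defaults)
  bcs <- gating_bcs(mesh, omesh, pull = spec$pull, increments = increments)
  traj <- tryCatch(
    solve_gating(mesh, conn, bcs, ...),
    error = function(e)
      stop("run_scenario: solver failed for scenario ", spec$id, ": ",
           conditionMessage(e)))
  met <- tm1_stress_metrics(traj)
  res <- structure(
    list(id = spec$id, spec = spec,
         pore_closed = met$pore_closed, pore_final = met$pore_final,
         opened = met$opened,
         threshold_MPa = met$threshold_MPa,
         open_state_MPa = met$open_state_MPa,
         onset_increment = met$onset_increment,
         helix_max_MPa = met$helix_max_MPa,
         converged = is.na(traj$truncated_at),
         truncated_at = traj$truncated_at),
    class = "scenario_result")
  res$feasibility <- feasibility_check(res, defaults$helices)
  if (keep_trajectory) res$trajectory <- traj
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result %d> pore %.1f -> %.1f A (%s)\n", x$id,
              x$pore_closed, x$pore_final,
              if (x$opened) "opened" else "locked"))
  if (x$opened)
    cat(sprintf("  threshold %.0f MPa, open-state %.0f MPa\n",
                x$threshold_MPa, x$open_state_MPa))
  fl <- names(x$feasibility)[x$feasibility == "exceeds elastic limit"]
  if (length(fl))
    cat("  exceeds elastic limit:", paste(fl, collapse = ", "), "\n")
  invisible(x)
}

#' Compare per-helix stresses with elastic capacities
#'
#' A helix's elastic capacity is the axial stress of its yield force
#' over the rod cross-section, [axial_stress()]. The verdict is
#' `"exceeds elastic limit"` when the scenario's maximum stress in that
#' helix is above capacity, `"within elastic limit"` otherwise.
#'
#' @param result a `scenario_result` (or any list with a
#'   `helix_max_MPa` named vector).
#' @param specs named list of [helix_spec()]s.
#' @return named character vector of verdicts.
#' @export
feasibility_check <- function(result, specs) {
  hm <- result$helix_max_MPa
  if (is.null(hm)) stop("feasibility_check: result carries no helix stresses")
  out <- vapply(names(hm), function(h) {
    sp <- specs[[h]]
    if (is.null(sp) || is.null(sp$yield_force))
      stop("feasibility_check: missing yield data for helix ", h)
    cap <- pN_A2_to_MPa(axial_stress(sp$yield_force, sp$radius))
    if (hm[[h]] > cap) "exceeds elastic limit" else "within elastic limit"
  }, "")
  names(out) <- names(hm)
  out
}

#' Tabulate scenario results
#'
#' One row per scenario with pore size and the two TM1 stress metrics,
#' mirroring the layout of the reduction/deletion result tables;
#' entries for scenarios that did not open are absent (`NA`, rendered
#' as `"-"` in the TSV form).
#'
#' @param results list of `scenario_result`s (empty list allowed).
#' @return data.frame with columns `model`, `pull`, `reduction`,
#'   `deletions`, `pore_A`, `threshold_MPa`, `open_state_MPa`,
#'   `opened`.
#' @export
tabulate_results <- function(results) {
  cols <- function(r) data.frame(
    model = r$id,
    pull = r$spec$pull,
    reduction = if (is.na(r$spec$rho)) "G22N" else
      sprintf("%.0f%%", 100 * r$spec$rho),
    deletions = if (length(r$spec$deletions))
      paste(r$spec$deletions, collapse = "+") else "",
    pore_A = r$pore_final,
    threshold_MPa = r$threshold_MPa,
    open_state_MPa = r$open_state_MPa,
    opened = r$opened,
    stringsAsFactors = FALSE)
  if (!length(results))
    return(data.frame(model = integer(), pull = character(),
                      reduction = character(), deletions = character(),
                      pore_A = numeric(), threshold_MPa = numeric(),
                      open_state_MPa = numeric(), opened = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(results, cols))
}
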