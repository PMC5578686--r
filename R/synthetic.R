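#' Synthetic study conditions
#'
#' All inputs the pipeline needs can be generated synthetically with the
#' statistical structure the analysis assumes: 12-6 interaction wells
#' with genotype-dependent depths and equilibrium shifts for the five
#' pore-lock belts, linear-then-plastic helix constitutive behaviour,
#' and reversible/irreversible load-unload traces. `synthetic_defaults()`
#' is the single source of those conditions.
#'
#' Belt equilibrium distances equal the closed-state WT anchor
#' separations of the idealized geometry, so the resting channel is an
#' exact equilibrium of the pore-lock. Well depths (unobservable
#' absolutes; only ratios and shapes matter downstream) lie in
#' 0.5-2.5 kcal/mol with the V16-G22 belt the deepest. The G22N
#' peak-to-peak reduction fractions are 0.82 (V16-G22), 0.43 (L19-L19),
#' 0.00 (A20-G22), 0.31 (V23-V23) and 0.40 (V23-G26); the mutant
#' equilibrium right-shift defaults to +0.5 A except for the symmetric
#' L19-L19 contact.
#'
#' Helix moduli are 0.5 (N), 2.2 (TM1), 2.0 (TM2) and 3.0 (C) GPa,
#' satisfying E(C) > E(TM1) ~ E(TM2) > 4 E(N). TM1 yields at 400 pN and
#' 30% strain (50 A reference length) with a 4 A plastic residual; the
#' plastic branch slope is 10% of the elastic slope.
#'
#' @param seed default random seed used by the noisy generators.
#' @return a `synthetic_defaults` list with components `belts`
#'   (data.frame), `helices` (list of [helix_spec()]), `curve`
#'   (sampling controls), `trace` (plasticity controls), `geometry`
#'   ([geometry_params()]) and `seed`.
#' @export
synthetic_defaults <- function(seed = 1L) {
  gp <- geometry_params()
  geom <- gen_geometry("WT", "closed", gp)
  belts <- data.frame(
    belt = c("V16-G22", "L19-L19", "A20-G22", "V23-V23", "V23-G26"),
    res_a = c(16, 19, 20, 23, 23),
    res_b = c(22, 19, 22, 23, 26),
    depth_wt = c(2.5, 1.9, 0.7, 1.3, 2.4),      # kcal/mol, V16-G22 deepest
    g22n_reduction = c(0.82, 0.43, 0.00, 0.31, 0.40),
    g22n_shift = c(0.5, 0.0, 0.5, 0.5, 0.5),    # A, right shift
    stringsAsFactors = FALSE)
  belts$r_eq <- belt_anchor_distance(geom, belts$res_a, belts$res_b)
  stopifnot(all(belts$depth_wt > 0), all(belts$r_eq > 0))

  # pN/A^2 (x0.1 GPa); N slightly under 1/4 of the transmembrane moduli
  # so that both TM helices are strictly more than 4x stiffer
  E <- c(N = 4.8, TM1 = 22, TM2 = 20, C = 30)
  ys <- c(N = 0.10, TM1 = 0.30, TM2 = 0.30, C = 0.25)
  A <- pi * 2.5^2
  # TM1 yield force is the measured 400 pN; the others follow E*A*eps_y.
  yf <- c(N = E[["N"]] * A * ys[["N"]],
          TM1 = 400,
          TM2 = E[["TM2"]] * A * ys[["TM2"]],
          C = E[["C"]] * A * ys[["C"]])
  len <- c(N = gp$n_length, TM1 = gp$tm1_length, TM2 = gp$tm2_length,
           C = gp$c_length)
  refl <- c(N = gp$n_length, TM1 = 50, TM2 = gp$tm2_length, C = gp$c_length)
  helices <- lapply(c("N", "TM1", "TM2", "C"), function(h)
    helix_spec(h, length = len[[h]], E = E[[h]], yield_strain = ys[[h]],
               yield_force = yf[[h]], ref_length = refl[[h]]))
  names(helices) <- c("N", "TM1", "TM2", "C")

  structure(
    list(belts = belts,
         helices = helices,
         curve = list(span = c(0.8, 3.0), n_points = 60L),
         trace = list(plastic_slope_frac = 0.1, plastic_residual = 4.0,
                      n_load = 60L, n_unload = 40L),
         geometry = gp,
         seed = as.integer(seed)),
    class = "synthetic_defaults")
}

#' @export
print.synthetic_defaults <- function(x, ...) {
  cat("<synthetic_defaults>\n")
  print(x$belts[, c("belt", "depth_wt", "r_eq", "g22n_reduction", "g22n_shift")])
  cat("helix E (pN/A^2):",
      paste(sprintf("%s=%g", names(x$helices),
                    vapply(x$helices, `[[`, 0, "E")), collapse = ", "), "\n")
  invisible(x)
}

# evaluate fn with a local RNG state so generators do not disturb the
# caller's random stream
.with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Nominal force law of a belt under the synthetic defaults
#'
#' The exact 12-6 law (depth, equilibrium distance) for a belt and
#' genotype; the G22N law has its depth scaled by (1 - reduction) and,
#' when `shift` is `TRUE`, the equilibrium shifted right.
#'
#' @param pair belt label.
#' @param genotype `"WT"` or `"G22N"`.
#' @param defaults a [synthetic_defaults()] object.
#' @param shift apply the G22N equilibrium right-shift (default `TRUE`
#'   for curve generation; scenario runs scale strength only).
#' @return a `force_law` (`zero_force_law` for a fully reduced belt).
#' @export
belt_law <- function(pair, genotype = c("WT", "G22N"),
                     defaults = synthetic_defaults(), shift = TRUE) {
  genotype <- match.arg(genotype)
  b <- defaults$belts
  i <- match(pair, b$belt)
  if (is.na(i))
    stop("unknown belt '", pair, "'; belts are: ",
         paste(b$belt, collapse = ", "))
  depth <- b$depth_wt[i]
  r_eq <- b$r_eq[i]
  if (genotype == "G22N") {
    red <- b$g22n_reduction[i]
    if (red >= 1) return(apply_reduction(law_from_well(depth, r_eq,
                                                       pair = pair,
                                                       genotype = genotype), 1))
    depth <- depth * (1 - red)
    if (shift) r_eq <- r_eq + b$g22n_shift[i]
  }
  law_from_well(depth, r_eq, pair = pair, genotype = genotype)
}

#' Generate a synthetic pairwise interaction curve
#'
#' Samples the belt's nominal 12-6 law over `span * r_eq`
#' (default 0.8-3 times the equilibrium distance, always including the
#' equilibrium point itself so the sampled minimum equals the configured
#' depth exactly) and adds independent Gaussian noise: `noise_sd` in
#' kcal/mol on the energy channel and `noise_sd` (converted from
#' kcal/mol/A) on the force channel. Identical seeds give identical
#' output.
#'
#' @param pair one of the five belt labels.
#' @param genotype `"WT"` or `"G22N"`.
#' @param n_points number of samples (>= 10).
#' @param noise_sd Gaussian noise standard deviation (>= 0; 0 = exact).
#' @param seed integer seed.
#' @param defaults a [synthetic_defaults()] object.
#' @return an `interaction_curve` with both energy and force channels.
#' @export
#' @examples
#' wt <- gen_interaction_curve("L19-L19", "WT")
#' mu <- gen_interaction_curve("L19-L19", "G22N")
#' peak_to_peak_reduction(wt, mu) # 43
gen_interaction_curve <- function(pair, genotype = c("WT", "G22N"),
                                  n_points = NULL, noise_sd = 0,
                                  seed = NULL,
                                  defaults = synthetic_defaults()) {
  genotype <- match.arg(genotype)
  if (is.null(n_points)) n_points <- defaults$curve$n_points
  if (is.null(seed)) seed <- defaults$seed
  if (n_points < 10L) stop("gen_interaction_curve: n_points must be >= 10")
  if (noise_sd < 0) stop("gen_interaction_curve: noise_sd must be >= 0")
  law <- belt_law(pair, genotype, defaults, shift = TRUE)
  r_eq <- law_r_eq(law)
  r <- sort(unique(c(seq(defaults$curve$span[1] * r_eq,
                         defaults$curve$span[2] * r_eq,
                         length.out = n_points - 1L), r_eq)))
  e <- lj_energy(law, r)
  f <- lj_force(law, r)
  if (noise_sd > 0) {
    noise <- .with_seed(seed, function() {
      list(e = stats::rnorm(length(r), 0, noise_sd),
           f = stats::rnorm(length(r), 0, kcalmol_per_A_to_pN(noise_sd)))
    })
    e <- e + noise$e
    f <- f + noise$f
  }
  interaction_curve(r, energy = e, force = f, pair = pair, genotype = genotype)
}

#' Generate a synthetic helix stress-strain curve
#'
#' Noiseless behaviour is linear, `sigma = E * eps`, up to the helix's
#' yield strain, then a plastic branch with 10% of the elastic slope.
#' Gaussian noise (`noise_sd`, pN/A^2) is added per sample.
#'
#' @param helix `"N"`, `"TM1"`, `"TM2"` or `"C"`.
#' @param max_strain maximum strain, in (0, 0.5].
#' @param noise_sd stress noise, pN/A^2.
#' @param seed integer seed.
#' @param n_points number of samples.
#' @param defaults a [synthetic_defaults()] object.
#' @return a `stress_strain_curve`.
#' @export
gen_stress_strain <- function(helix, max_strain = 0.06, noise_sd = 0,
                              seed = NULL, n_points = 60L,
                              defaults = synthetic_defaults()) {
  helix <- match.arg(helix, c("N", "TM1", "TM2", "C"))
  if (is.null(seed)) seed <- defaults$seed
  if (!(max_strain > 0 && max_strain <= 0.5))
    stop("gen_stress_strain: max_strain must be in (0, 0.5]")
  sp <- defaults$helices[[helix]]
  eps <- seq(0, max_strain, length.out = n_points)
  sig <- ifelse(eps <= sp$yield_strain,
                sp$E * eps,
                sp$E * sp$yield_strain +
                  defaults$trace$plastic_slope_frac * sp$E *
                  (eps - sp$yield_strain))
  if (noise_sd > 0)
    sig <- sig + .with_seed(seed, function() stats::rnorm(n_points, 0, noise_sd))
  stress_strain_curve(helix, eps, sig)
}

#' Generate a synthetic load-unload trace
#'
#' Loading follows the helix's force-elongation stiffness
#' `k = yield_force / (yield_strain * ref_length)` up to the peak, with
#' a reduced-slope plastic branch past yield. Unloading returns to zero
#' residual elongation when the peak strain is within the elastic limit,
#' and otherwise terminates at the configured plastic residual
#' elongation (default 4 A).
#'
#' @param helix helix label.
#' @param peak_strain peak engineering strain (>= 0).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param noise_sd optional Gaussian force noise, pN.
#' @param defaults a [synthetic_defaults()] object.
#' @return a `load_unload_trace`.
#' @export
#' @examples
#' classify_reversibility(gen_load_unload("TM1", 0.29))$class # elastic
#' classify_reversibility(gen_load_unload("TM1", 0.37))$residual # ~4
gen_load_unload <- function(helix, peak_strain, seed = NULL, noise_sd = 0,
                            defaults = synthetic_defaults()) {
  helix <- match.arg(helix, c("N", "TM1", "TM2", "C"))
  if (is.null(seed)) seed <- defaults$seed
  if (peak_strain < 0) stop("gen_load_unload: peak_strain must be >= 0")
  sp <- defaults$helices[[helix]]
  L0 <- sp$ref_length
  if (peak_strain == 0) {
    return(load_unload_trace(helix, c(0, 0), c(0, 0), 1L, L0))
  }
  k <- sp$yield_force / (sp$yield_strain * L0)
  frac <- defaults$trace$plastic_slope_frac
  dl_y <- sp$yield_strain * L0
  dl_peak <- peak_strain * L0
  f_of <- function(dl) ifelse(dl <= dl_y, k * dl,
                              sp$yield_force + frac * k * (dl - dl_y))
  dl_load <- seq(0, dl_peak, length.out = defaults$trace$n_load)
  if (dl_peak > dl_y) dl_load <- sort(unique(c(dl_load, dl_y)))
  f_load <- f_of(dl_load)
  plastic <- peak_strain > sp$yield_strain
  end_dl <- if (plastic) defaults$trace$plastic_residual else 0
  dl_un <- seq(dl_peak, end_dl, length.out = defaults$trace$n_unload)
  f_peak <- f_of(dl_peak)
  f_un <- if (dl_peak > end_dl)
    f_peak * (dl_un - end_dl) / (dl_peak - end_dl) else rep(0, length(dl_un))
  el <- c(dl_load, dl_un[-1L])
  fo <- c(f_load, f_un[-1L])
  if (noise_sd > 0) {
    fo <- fo + .with_seed(seed, function() stats::rnorm(length(fo), 0, noise_sd))
    fo <- pmax(fo, 0)
    fo[length(fo)] <- 0
  }
  load_unload_trace(helix, el, fo, peak_index = length(dl_load), ref_length = L0)
}
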