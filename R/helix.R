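#' Helix rod specifications
#'
#' Each MscL helix is treated as an elastic cylinder of radius 2.5 A.
#' Rod lengths follow the channel model: N-terminus 18.65 A, TM1
#' 47.33 A, TM2 42.51 A, C-terminus 36.06 A; Poisson's ratio 0.48
#' (recorded, not used by the rod stiffness). Young's moduli, yield
#' strains and yield forces are the synthetic defaults of
#' [synthetic_defaults()] unless overridden.
#'
#' Note that the yield force and yield strain are kept as independent
#' measurements (from uniaxial load-unload traces) and are not forced to
#' satisfy `F_y = E * A * eps_y`: the two characterizations of helix
#' mechanics come from different pulling protocols and use different
#' effective cross-sections.
#'
#' @param name one of `"N"`, `"TM1"`, `"TM2"`, `"C"`.
#' @param length rod length, angstrom.
#' @param radius rod radius, angstrom (default 2.5).
#' @param E Young's modulus, pN/A^2 (1 pN/A^2 = 100 MPa).
#' @param nu Poisson ratio (default 0.48).
#' @param yield_strain engineering strain at the elastic limit.
#' @param yield_force force at the elastic limit, pN.
#' @param ref_length reference length used for strain arithmetic on
#'   load-unload traces (for TM1 this is the 50 A stretched-segment
#'   reference, distinct from the 47.33 A rod length).
#' @return a `helix_spec`.
#' @export
helix_spec <- function(name, length, radius = 2.5, E, nu = 0.48,
                       yield_strain, yield_force,
                       ref_length = length) {
  name <- match.arg(name, c("N", "TM1", "TM2", "C"))
  stopifnot(length > 0, radius > 0, E > 0, nu > 0, nu < 0.5,
            yield_strain > 0, yield_force > 0, ref_length > 0)
  structure(list(name = name, length = length, radius = radius, E = E,
                 nu = nu, yield_strain = yield_strain,
                 yield_force = yield_force, ref_length = ref_length),
            class = "helix_spec")
}

#' @export
print.helix_spec <- function(x, ...) {
  cat(sprintf(
    "<helix_spec %s> L=%.2f A, r=%.2f A, E=%.3g pN/A^2 (%.2f GPa), yield %.0f pN @ %.0f%% strain\n",
    x$name, x$length, x$radius, x$E, x$E / 10, x$yield_force,
    100 * x$yield_strain))
  invisible(x)
}

#' Cross-sectional area of a helix rod
#' @param spec a `helix_spec` (or radius).
#' @return area in A^2.
#' @export
rod_area <- function(spec) {
  r <- if (inherits(spec, "helix_spec")) spec$radius else spec
  pi * r^2
}

#' Engineering strain
#'
#' `(length - reference_length) / reference_length`.
#'
#' @param length current length, angstrom.
#' @param reference_length undeformed length, angstrom (> 0).
#' @return strain (dimensionless fraction).
#' @export
#' @examples
#' engineering_strain(60, 50) # 0.20
#' engineering_strain(68.5, 50) # 0.37
engineering_strain <- function(length, reference_length) {
  if (any(reference_length <= 0))
    stop("engineering_strain: reference_length must be > 0")
  (length - reference_length) / reference_length
}

#' Axial stress of a rod under force
#'
#' `force / (pi * radius^2)` in pN/A^2 (multiply by 100 for MPa).
#'
#' @param force axial force, pN.
#' @param radius rod radius, angstrom (> 0).
#' @return stress in pN/A^2.
#' @export
#' @examples
#' pN_A2_to_MPa(axial_stress(196.3, 2.5)) # ~1000 MPa
axial_stress <- function(force, radius) {
  if (any(radius <= 0)) stop("axial_stress: radius must be > 0")
  force / (pi * radius^2)
}

#' Stress-strain curve container
#'
#' @param helix helix name (`"N"`, `"TM1"`, `"TM2"`, `"C"`).
#' @param strain strains (dimensionless, non-negative, increasing).
#' @param stress stresses, pN/A^2.
#' @return a `stress_strain_curve`.
#' @export
stress_strain_curve <- function(helix, strain, stress) {
  helix <- match.arg(helix, c("N", "TM1", "TM2", "C"))
  stopifnot(length(strain) == length(stress), strain[1] >= 0)
  if (is.unsorted(strain)) stop("stress_strain_curve: strains must increase")
  structure(list(helix = helix, strain = as.numeric(strain),
                 stress = as.numeric(stress)),
            class = "stress_strain_curve")
}

#' Load-unload trace container
#'
#' Ordered (elongation, force) samples covering a loading branch up to
#' the peak elongation, then an unloading branch back to zero force.
#'
#' @param helix helix name.
#' @param elongation elongations, angstrom.
#' @param force forces, pN (non-negative).
#' @param peak_index index of the peak-elongation sample separating
#'   loading from unloading.
#' @param ref_length reference length for strain arithmetic, angstrom.
#' @return a `load_unload_trace`.
#' @export
load_unload_trace <- function(helix, elongation, force, peak_index,
                              ref_length) {
  helix <- match.arg(helix, c("N", "TM1", "TM2", "C"))
  stopifnot(length(elongation) == length(force),
            peak_index >= 1L, peak_index <= length(force), ref_length > 0)
  if (any(force < -1e-9)) stop("load_unload_trace: forces must be >= 0")
  if (abs(force[length(force)]) > 1e-9)
    stop("load_unload_trace: unloading branch must end at zero force")
  structure(list(helix = helix, elongation = as.numeric(elongation),
                 force = as.numeric(force), peak_index = as.integer(peak_index),
                 ref_length = ref_length),
            class = "load_unload_trace")
}

#' Young's modulus from the low-strain limb of a stress-strain curve
#'
#' Slope of a least-squares line through the origin over samples with
#' `strain <= strain_cap`.
#'
#' @param curve a `stress_strain_curve`.
#' @param strain_cap upper strain for the linear fit (default 0.06).
#' @return modulus in pN/A^2.
#' @export
youngs_modulus <- function(curve, strain_cap = 0.06) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  keep <- curve$strain <= strain_cap & curve$strain >= 0
  eps <- curve$strain[keep]
  sig <- curve$stress[keep]
  pos <- eps > 0
  if (sum(pos) < 3L)
    stop("youngs_modulus: need >= 3 samples with 0 < strain <= ", strain_cap)
  sum(sig[pos] * eps[pos]) / sum(eps[pos]^2)
}

#' Elastic limit from a loading trace
#'
#' Scans the loading branch for the slope-break point: the last sample
#' before the local slope first drops below `slope_frac` (default 50%)
#' of the initial slope. Returns `reached = FALSE` when no break occurs
#' within the trace ("limit not reached").
#'
#' @param trace a `load_unload_trace` (its loading branch is used) or a
#'   two-column matrix/data.frame of (elongation, force).
#' @param reference_length reference length for strain; defaults to the
#'   trace's own `ref_length`.
#' @param slope_frac slope-drop threshold as a fraction of the initial
#'   slope (default 0.5).
#' @return list with `reached`, `force` (pN), `strain`, `elongation` (A).
#' @export
elastic_limit <- function(trace, reference_length = NULL, slope_frac = 0.5) {
  if (inherits(trace, "load_unload_trace")) {
    el <- trace$elongation[seq_len(trace$peak_index)]
    fo <- trace$force[seq_len(trace$peak_index)]
    if (is.null(reference_length)) reference_length <- trace$ref_length
  } else {
    m <- as.matrix(trace)
    el <- m[, 1]; fo <- m[, 2]
    if (is.null(reference_length))
      stop("elastic_limit: reference_length required for raw traces")
  }
  if (reference_length <= 0) stop("elastic_limit: reference_length must be > 0")
  if (length(el) < 4L) stop("elastic_limit: loading branch too short")
  d_el <- diff(el)
  ok <- d_el > 0
  slopes <- diff(fo)[ok] / d_el[ok]
  idx_map <- which(ok)
  init <- stats::median(slopes[seq_len(min(3L, length(slopes)))])
  if (init <= 0) stop("elastic_limit: non-positive initial slope")
  brk <- which(slopes < slope_frac * init)
  if (!length(brk))
    return(list(reached = FALSE, force = NA_real_, strain = NA_real_,
                elongation = NA_real_))
  i <- idx_map[brk[1]] # last sample before the soft branch
  list(reached = TRUE, force = fo[i], strain = el[i] / reference_length,
       elongation = el[i])
}

#' Classify a load-unload trace as elastic or plastic
#'
#' Elastic iff the residual elongation where the unloading branch
#' reaches zero force is within `residual_tol` (default 1 A) of zero.
#'
#' @param trace a `load_unload_trace`.
#' @param residual_tol residual-elongation tolerance, angstrom.
#' @return list with `class` (`"elastic"`/`"plastic"`) and `residual` (A).
#' @export
classify_reversibility <- function(trace, residual_tol = 1.0) {
  stopifnot(inherits(trace, "load_unload_trace"))
  k <- length(trace$force)
  if (trace$peak_index >= k && trace$force[k] > 1e-9)
    stop("classify_reversibility: trace has no unloading branch")
  residual <- trace$elongation[k] # unloading ends at zero force
  cls <- if (abs(residual) <= residual_tol) "elastic" else "plastic"
  list(class = cls, residual = residual)
}

#' Read / write stress-strain and load-unload traces as TSV
#'
#' `write_trace_file()` writes either container; `read_stress_strain_file()`
#' and `read_load_unload_file()` read them back. Columns are
#' `strain`, `stress_pN_A2` for stress-strain curves and
#' `elongation_A`, `force_pN` for load-unload traces.
#'
#' @param trace a `stress_strain_curve` or `load_unload_trace`.
#' @param path file path.
#' @return `path` invisibly (writer); the container (readers).
#' @export
write_trace_file <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(trace, "stress_strain_curve")) {
    writeLines(sprintf("# stress-strain helix=%s", trace$helix), con)
    utils::write.table(
      format(data.frame(strain = trace$strain,
                        stress_pN_A2 = trace$stress),
             digits = 12, trim = TRUE),
      con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(trace, "load_unload_trace")) {
    writeLines(sprintf("# load-unload helix=%s peak_index=%d ref_length=%.6g",
                       trace$helix, trace$peak_index, trace$ref_length), con)
    utils::write.table(
      format(data.frame(elongation_A = trace$elongation,
                        force_pN = trace$force),
             digits = 12, trim = TRUE),
      con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop("write_trace_file: unsupported object")
  invisible(path)
}

#' @rdname write_trace_file
#' @param helix helix label for the returned container.
#' @export
read_stress_strain_file <- function(path, helix) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("strain", "stress_pN_A2") %in% names(df)))
    stop("read_stress_strain_file: need columns strain, stress_pN_A2")
  stress_strain_curve(helix, df$strain, df$stress_pN_A2)
}

#' @rdname write_trace_file
#' @export
read_load_unload_file <- function(path, helix) {
  hdr <- readLines(path, n = 1L)
  pk <- as.integer(sub(".*peak_index=(\\d+).*", "\\1", hdr))
  rl <- as.numeric(sub(".*ref_length=([0-9.eE+-]+).*", "\\1", hdr))
  if (is.na(pk) || is.na(rl))
    stop("read_load_unload_file: header must carry peak_index and ref_length")
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("elongation_A", "force_pN") %in% names(df)))
    stop("read_load_unload_file: need columns elongation_A, force_pN")
  load_unload_trace(helix, df$elongation_A, df$force_pN, pk, rl)
}
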