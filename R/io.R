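#' Geometry, report and configuration I/O
#'
#' Geometries travel as PDB (one pseudo-atom per centerline point,
#' record name CA, chains A-E -- a visualization convention, not a
#' claim of atomic structure) or JSON; scenario reports as JSON + TSV
#' with a config echo and seed; run configuration as a YAML file with
#' a fixed key schema (unknown keys are rejected, never ignored).
#'
#' @name msclrod-io
NULL

.HELIX_ORDER <- c("N", "TM1", "TM2", "C")

#' Write a channel geometry as a PDB file
#'
#' Each centerline point becomes a CA pseudo-atom; subunits map to
#' chains A-E and helices carry their residue numbering (N 1-14,
#' TM1 15-48, TM2 70-100, C 105-125 by default).
#'
#' @param geometry a `channel_geometry`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geometry_pdb <- function(geometry, path) {
  stopifnot(inherits(geometry, "channel_geometry"))
  xyz <- c(); resno <- c(); chain <- c()
  chains <- LETTERS[1:5]
  for (k in 1:5) for (h in .HELIX_ORDER) {
    poly <- geometry$subunits[[k]][[h]]
    xyz <- c(xyz, as.vector(t(poly[, 1:3])))
    resno <- c(resno, attr(poly, "residues"))
    chain <- c(chain, rep(chains[k], nrow(poly)))
  }
  n <- length(resno)
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, chain = chain,
                   resid = rep("ALA", n), elety = rep("CA", n),
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' Read a channel geometry from a PDB file
#'
#' Rebuilds per-helix centerline polylines from the C-alpha records of
#' five chains, using declared residue ranges per helix. The channel
#' axis is the best-fit symmetry axis: the normal of the plane through
#' the five chain centroids, oriented along the original +z sense, with
#' the centroid ring's center as origin. Missing chains or residues are
#' reported explicitly.
#'
#' @param path PDB file path.
#' @param chains chain identifiers mapping to subunits 1-5.
#' @param residue_ranges named list of residue vectors per helix
#'   (defaults match [write_geometry_pdb()]).
#' @return a `channel_geometry` (state `"imported"`).
#' @export
read_pdb_geometry <- function(path, chains = LETTERS[1:5],
                              residue_ranges = list(
                                N = 1:14, TM1 = 15:48,
                                TM2 = 70:100, C = 105:125)) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  ca <- pdb$atom[pdb$atom$elety == "CA", , drop = FALSE]
  missing_ch <- setdiff(chains, unique(ca$chain))
  if (length(missing_ch))
    stop("read_pdb_geometry: missing chain(s): ",
         paste(missing_ch, collapse = ", "))

  get_poly <- function(ch, res) {
    rows <- ca[ca$chain == ch & ca$resno %in% res, , drop = FALSE]
    miss <- setdiff(res, rows$resno)
    if (length(miss))
      stop("read_pdb_geometry: chain ", ch, " lacks residue(s) ",
           paste(utils::head(miss, 8), collapse = ", "))
    rows <- rows[order(rows$resno), , drop = FALSE]
    P <- as.matrix(rows[, c("x", "y", "z")])
    dimnames(P) <- list(NULL, c("x", "y", "z"))
    seg <- sqrt(rowSums(diff(P)^2))
    .polyline(P, c(0, cumsum(seg)), rows$resno)
  }

  subunits <- lapply(chains, function(ch)
    stats::setNames(lapply(.HELIX_ORDER, function(h)
      get_poly(ch, residue_ranges[[h]])), .HELIX_ORDER))

  # symmetry axis from the ring of subunit centroids
  cent <- t(vapply(subunits, function(su)
    colMeans(do.call(rbind, lapply(su, function(p) p[, 1:3]))), numeric(3)))
  center <- colMeans(cent)
  sv <- svd(sweep(cent, 2, center))
  axis <- sv$v[, 3]
  # orient consistently: points should ascend along the axis as along +z
  ref <- subunits[[1]]$TM1
  if (sum((ref[nrow(ref), ] - ref[1, ]) * axis) < 0) axis <- -axis
  structure(
    list(genotype = NA_character_, state = "imported",
         params = geometry_params(), axis = axis, center = center,
         subunits = subunits),
    class = "channel_geometry")
}

#' Write a channel geometry as JSON
#' @param geometry a `channel_geometry`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geometry_json <- function(geometry, path) {
  stopifnot(inherits(geometry, "channel_geometry"))
  out <- list(
    genotype = geometry$genotype, state = geometry$state,
    axis = geometry$axis, center = geometry$center,
    subunits = lapply(geometry$subunits, function(su)
      lapply(su, function(p)
        list(coords = unname(as.matrix(p[, 1:3])),
             arclength = as.numeric(attr(p, "arclength")),
             residues = as.numeric(attr(p, "residues"))))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 12)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML with the fixed top-level schema `seed`, `scenario`, `solver`,
#' `belts`, `helices`, `geometry`, `output`, `units`. Unknown keys are
#' rejected. The returned object is a validated list merged over the
#' package defaults.
#'
#' @param path YAML file path.
#' @return a named list (`run_config`).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "scenario", "solver", "belts", "helices", "geometry",
             "output", "units")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("read_config: unknown key(s): ", paste(unknown, collapse = ", "),
         "; known keys are: ", paste(known, collapse = ", "))
  if (!is.null(cfg$units) && !cfg$units %in% c("MPa", "pN_A2"))
    stop("read_config: units must be 'MPa' or 'pN_A2'")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "run_config")
}

#' Apply configuration overrides to the synthetic defaults
#'
#' Belt depths (`belts: {<label>: depth}`), helix moduli
#' (`helices: {<name>: E}`, pN/A^2) and geometry parameters
#' (`geometry: {open_elongation: ...}`) can be overridden from a
#' [read_config()] object.
#'
#' @param cfg a `run_config`.
#' @param defaults base [synthetic_defaults()].
#' @return modified `synthetic_defaults`.
#' @export
apply_config <- function(cfg, defaults = synthetic_defaults()) {
  if (!is.null(cfg$seed)) defaults$seed <- as.integer(cfg$seed)
  for (b in names(cfg$belts)) {
    i <- match(b, defaults$belts$belt)
    if (is.na(i)) stop("apply_config: unknown belt '", b, "'")
    defaults$belts$depth_wt[i] <- as.numeric(cfg$belts[[b]])
  }
  for (h in names(cfg$helices)) {
    if (!h %in% names(defaults$helices))
      stop("apply_config: unknown helix '", h, "'")
    defaults$helices[[h]]$E <- as.numeric(cfg$helices[[h]])
  }
  for (g in names(cfg$geometry)) {
    if (!g %in% names(defaults$geometry))
      stop("apply_config: unknown geometry parameter '", g, "'")
    defaults$geometry[[g]] <- cfg$geometry[[g]]
  }
  defaults
}

.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE)
  unname(tools::md5sum(tf))
}

#' Write a scenario report (JSON + TSV)
#'
#' Produces `<path>.json` (full metrics, config echo, seed, config
#' hash) and `<path>.tsv` (the scenario table, absent stress entries
#' rendered as `-`). Serialization is deterministic: identical inputs
#' give byte-identical files.
#'
#' @param results list of `scenario_result`s.
#' @param config configuration list echoed into the report (include the
#'   seed used; a `seed` element is required).
#' @param path output path prefix (without extension).
#' @return named character vector of the two file paths, invisibly.
#' @export
write_report <- function(results, config, path) {
  if (is.null(config$seed))
    stop("write_report: config must carry the seed")
  tab <- tabulate_results(results)
  hash <- .config_hash(config)
  json_path <- paste0(path, ".json")
  tsv_path <- paste0(path, ".tsv")
  payload <- list(
    config = config,
    config_md5 = hash,
    seed = config$seed,
    scenarios = lapply(results, function(r) list(
      model = r$id, pull = r$spec$pull,
      reduction = if (is.na(r$spec$rho)) "G22N" else r$spec$rho,
      deletions = r$spec$deletions,
      pore_closed_A = r$pore_closed, pore_final_A = r$pore_final,
      opened = r$opened,
      threshold_MPa = r$threshold_MPa,
      open_state_MPa = r$open_state_MPa,
      helix_max_MPa = as.list(r$helix_max_MPa),
      feasibility = as.list(r$feasibility),
      converged = r$converged)))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE, na = "null")
  con <- file(tsv_path, "w")
  writeLines(sprintf("# msclrod scenario report; seed=%s config_md5=%s",
                     format(config$seed), hash), con)
  ftab <- tab
  for (cn in c("threshold_MPa", "open_state_MPa"))
    ftab[[cn]] <- ifelse(is.na(tab[[cn]]), "-", sprintf("%.1f", tab[[cn]]))
  ftab$pore_A <- sprintf("%.2f", tab$pore_A)
  utils::write.table(ftab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(c(json = json_path, tsv = tsv_path))
}

#' Read back a scenario report table
#' @param path path prefix used in [write_report()].
#' @return data.frame in the [tabulate_results()] layout.
#' @export
read_report_table <- function(path) {
  df <- utils::read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  for (cn in c("threshold_MPa", "open_state_MPa"))
    df[[cn]] <- suppressWarnings(as.numeric(ifelse(df[[cn]] == "-", NA,
                                                   df[[cn]])))
  df
}
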