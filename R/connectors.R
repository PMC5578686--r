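#' The van der Waals pore-lock connector network
#'
#' The closed pore is constrained by five concentric pentagonal "belts"
#' of pairwise hydrophobic contacts between neighbouring TM1 helices
#' (A20-G22, V23-G26, L19-L19, V23-V23, V16-G22). Each belt contributes
#' one connector per subunit pair, 25 in the full wild-type lock. A
#' connector transmits its force law along the line joining its two
#' anchor residues, equal and opposite on each end.
#'
#' @name porelock
NULL

.BELTS <- c("V16-G22", "L19-L19", "A20-G22", "V23-V23", "V23-G26")

#' Assemble the pore-lock connector set
#'
#' One connector per (belt, subunit pair), excluding deleted belts;
#' anchor residues are taken from the belt table of
#' [synthetic_defaults()] (residue `res_a` on subunit `s`, `res_b` on
#' subunit `s + 1 mod 5`). A uniform strength reduction `rho` is applied
#' to every remaining law.
#'
#' @param geometry a `channel_geometry` (validates that anchors lie on
#'   the TM1 polylines).
#' @param laws named list of `force_law` objects, one per belt label; by
#'   default the nominal WT laws of [belt_law()].
#' @param deletions character vector of belt labels to remove (e.g.
#'   `"V23-G26"` for the G26 deletion variant).
#' @param rho uniform reduction fraction in `[0, 1]`.
#' @param defaults a [synthetic_defaults()] object (anchor table).
#' @return a `connector_set`: data.frame with columns `subunit` (0-4),
#'   `belt`, `res_a`, `res_b` and a `law` list-column.
#' @export
#' @examples
#' g <- gen_geometry("WT", "closed")
#' nrow(build_porelock(g))                             # 25
#' nrow(build_porelock(g, deletions = "V23-G26"))      # 20
build_porelock <- function(geometry, laws = NULL, deletions = character(),
                           rho = 0, defaults = synthetic_defaults()) {
  stopifnot(inherits(geometry, "channel_geometry"))
  bt <- defaults$belts
  if (length(deletions)) {
    bad <- setdiff(deletions, bt$belt)
    if (length(bad))
      stop("build_porelock: unknown belt label(s) in deletions: ",
           paste(bad, collapse = ", "))
  }
  keep <- !(bt$belt %in% deletions)
  bt <- bt[keep, , drop = FALSE]
  if (is.null(laws)) {
    laws <- lapply(bt$belt, belt_law, genotype = "WT", defaults = defaults)
    names(laws) <- bt$belt
  }
  missing <- setdiff(bt$belt, names(laws))
  if (length(missing))
    stop("build_porelock: no force law provided for belt(s): ",
         paste(missing, collapse = ", "))
  # validate anchors against the geometry
  belt_anchor_distance(geometry, bt$res_a, bt$res_b)

  out <- if (nrow(bt)) {
    do.call(rbind, lapply(seq_len(nrow(bt)), function(i) {
      data.frame(subunit = 0:4, belt = bt$belt[i],
                 res_a = bt$res_a[i], res_b = bt$res_b[i],
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(subunit = integer(), belt = character(),
               res_a = integer(), res_b = integer(),
               stringsAsFactors = FALSE)
  }
  out$law <- lapply(out$belt, function(b) apply_reduction(laws[[b]], rho))
  class(out) <- c("connector_set", class(out))
  out
}

#' @export
print.connector_set <- function(x, ...) {
  cat(sprintf("<connector_set> %d connectors over belts: %s\n", nrow(x),
              paste(unique(x$belt), collapse = ", ")))
  invisible(x)
}

#' Evaluate connector anchor forces at a configuration
#'
#' For each connector, the force law is evaluated at the current
#' anchor-to-anchor distance and directed along the line of centers.
#' Returns per-connector force vectors on both anchors (Newton's third
#' law: they are exactly opposite).
#'
#' @param connectors a `connector_set`.
#' @param mesh a mesh from [discretize()] (for anchor node lookup).
#' @param X node coordinate matrix (defaults to the mesh rest state).
#' @return list with `r` (distances, A), `f` (signed force magnitudes,
#'   pN, positive = repulsive), `on_a`, `on_b` (n x 3 force matrices,
#'   pN) and node indices `node_a`, `node_b`.
#' @export
connector_forces <- function(connectors, mesh, X = mesh$X0) {
  idx <- resolve_connectors(connectors, mesh)
  d <- X[idx$node_b, , drop = FALSE] - X[idx$node_a, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  u <- d / r
  f <- vapply(seq_len(nrow(idx)), function(i)
    connector_force(connectors$law[[i]], r[i]), 0)
  # repulsive (f > 0) pushes b away from a
  on_b <- u * f
  list(r = r, f = f, on_a = -on_b, on_b = on_b,
       node_a = idx$node_a, node_b = idx$node_b)
}

#' Resolve connector anchors to mesh node indices
#' @keywords internal
resolve_connectors <- function(connectors, mesh) {
  look <- mesh$anchor_lookup
  key_a <- paste(connectors$subunit, connectors$res_a)
  key_b <- paste((connectors$subunit + 1L) %% 5L, connectors$res_b)
  node_a <- look[key_a]
  node_b <- look[key_b]
  if (anyNA(node_a) || anyNA(node_b))
    stop("resolve_connectors: anchor residue without a mesh node; ",
         "missing: ",
         paste(unique(c(key_a[is.na(node_a)], key_b[is.na(node_b)])),
               collapse = ", "))
  data.frame(node_a = unname(node_a), node_b = unname(node_b))
}
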