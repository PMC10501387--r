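#' Total branch length of a filament tree
#'
#' Sum over all non-root nodes of the Euclidean distance to the parent node,
#' in micrometres — the total process (cable) length of the reconstruction.
#'
#' @param tree a [FilamentTree-class].
#' @return total length in micrometres.
#' @export
totalBranchLength <- function(tree) {
  nd <- treeNodes(tree)
  if (nrow(nd) == 0L) stop("empty tree")
  nonroot <- !is.na(nd$parent)
  if (!any(nonroot)) return(0)
  pidx <- match(nd$parent[nonroot], nd$id)
  sum(sqrt((nd$x[nonroot] - nd$x[pidx])^2 +
           (nd$y[nonroot] - nd$y[pidx])^2 +
           (nd$z[nonroot] - nd$z[pidx])^2))
}

#' Sholl intersection curve of a filament tree
#'
#' Counts, for each concentric shell of radius `k * step` centred on the
#' root (soma) node, the number of parent-child segments whose endpoint
#' distances from the root straddle the shell: one endpoint at distance
#' `< r` and the other at distance `>= r` (the shell boundary belongs to
#' the outer side). A segment spanning several shells contributes once to
#' each shell it spans. The curve extends to the first shell beyond the
#' farthest node.
#'
#' For `dimension = 2` the tree is projected onto the x-y plane first
#' (z ignored), matching Sholl analysis of 2D epifluorescence images.
#'
#' @param tree a [FilamentTree-class].
#' @param step shell spacing in micrometres (default 5).
#' @param dimension 2 or 3.
#' @return a [ShollCurve-class].
#' @export
shollIntersections <- function(tree, step = 5, dimension = 3L) {
  if (length(step) != 1L || !is.finite(step) || step <= 0)
    stop("step must be > 0")
  dimension <- as.integer(dimension)
  if (!dimension %in% c(2L, 3L)) stop("dimension must be 2 or 3")
  nd <- treeNodes(tree)
  ridx <- match(rootId(tree), nd$id)
  dz <- if (dimension == 3L) nd$z - nd$z[ridx] else 0
  d <- sqrt((nd$x - nd$x[ridx])^2 + (nd$y - nd$y[ridx])^2 + dz^2)
  nshell <- floor(max(d) / step) + 1L   # first shell beyond the farthest node
  counts <- integer(nshell)
  nonroot <- which(!is.na(nd$parent))
  if (length(nonroot) > 0L) {
    pidx <- match(nd$parent[nonroot], nd$id)
    dmin <- pmin(d[nonroot], d[pidx])
    dmax <- pmax(d[nonroot], d[pidx])
    # shells k with dmin < k*step <= dmax
    k1 <- floor(dmin / step + 1e-12) + 1L
    k2 <- floor(dmax / step + 1e-12)
    has <- k2 >= k1
    if (any(has)) {
      # difference-array trick: +1 at k1, -1 after k2, then cumsum
      inc <- tabulate(k1[has], nbins = nshell + 1L) -
             tabulate(k2[has] + 1L, nbins = nshell + 1L)
      counts <- as.integer(cumsum(inc))[seq_len(nshell)]
    }
  }
  shollCurve(step = step, counts = counts, dimension = dimension)
}

#' Peak of a Sholl curve
#'
#' The maximum intersection count and the smallest radius attaining it
#' (ties break to the smaller radius). An all-zero curve reports a peak of
#' 0 at the first radius.
#'
#' @param curve a [ShollCurve-class].
#' @return named numeric vector `c(peak_radius=, peak_count=)`.
#' @export
peakOfCurve <- function(curve) {
  counts <- shollCounts(curve)
  if (length(counts) == 0L) stop("empty curve")
  i <- which.max(counts)
  c(peak_radius = shollRadii(curve)[i], peak_count = as.numeric(counts[i]))
}

#' Convex-hull territory volume of a filament tree
#'
#' Volume (cubic micrometres) of the 3D convex hull of all node
#' coordinates — a proxy for the tissue territory the astrocyte occupies.
#' Degenerate geometry (< 4 points, or all points coplanar) raises an error
#' rather than returning 0, to surface tracing problems.
#'
#' @param tree a [FilamentTree-class].
#' @return hull volume in cubic micrometres.
#' @export
convexHullTerritory <- function(tree) {
  nd <- treeNodes(tree)
  convexHullVolume3d(cbind(nd$x, nd$y, nd$z))
}

#' Per-cell morphometric summary
#'
#' Computes total branch length, territory volume and the Sholl peak for
#' one reconstructed cell, with its metadata labels.
#'
#' @param tree a [FilamentTree-class].
#' @param step Sholl shell spacing (micrometres).
#' @param dimension Sholl dimension (2 or 3).
#' @param territory compute the convex-hull territory volume (needs >= 4
#'   non-coplanar nodes)? If `FALSE` the column is `NA`.
#' @param cell_id,condition,animal,experiment,layer,timepoint labels copied
#'   into the output row.
#' @return one-row data.frame with columns `cell_id`, `condition`, `animal`,
#'   `experiment`, `layer`, `timepoint`, `total_length_um`, `territory_um3`,
#'   `peak_radius_um`, `peak_count`.
#' @export
cellMetrics <- function(tree, step = 5, dimension = 3L, territory = TRUE,
                        cell_id = NA_character_, condition = NA_character_,
                        animal = NA_character_, experiment = NA_character_,
                        layer = NA_character_, timepoint = NA_character_) {
  curve <- shollIntersections(tree, step = step, dimension = dimension)
  pk <- peakOfCurve(curve)
  data.frame(cell_id = cell_id, condition = condition, animal = animal,
             experiment = experiment, layer = layer, timepoint = timepoint,
             total_length_um = totalBranchLength(tree),
             territory_um3 = if (territory) convexHullTerritory(tree) else NA_real_,
             peak_radius_um = unname(pk["peak_radius"]),
             peak_count = unname(pk["peak_count"]),
             stringsAsFactors = FALSE)
}
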