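#' @import methods
NULL

#' FilamentTree: a rooted 3D reconstruction of a traced cell
#'
#' A rooted tree of 3D node positions (micrometres) with per-node radii, as
#' produced by filament tracing of an astrocyte. The root node is the soma
#' centre; every other node is connected to its parent by a straight segment.
#'
#' @slot nodes data.frame with columns `id` (integer, unique), `type`
#'   (integer SWC structure code, kept for round-tripping), `x`, `y`, `z`
#'   (numeric, micrometres), `radius` (numeric, micrometres, >= 0) and
#'   `parent` (integer id of the parent node; `NA` for the root).
#' @slot rootId integer id of the root (soma) node.
#'
#' @details Validity enforces: exactly one root; every non-root parent id
#'   exists; node ids unique; the parent relation is acyclic; and every
#'   node-to-parent segment has finite, strictly positive length.
#'
#' @export
setClass("FilamentTree",
  representation(nodes = "data.frame", rootId = "integer"),
  validity = function(object) {
    nd <- object@nodes
    req <- c("id", "type", "x", "y", "z", "radius", "parent")
    if (!all(req %in% names(nd)))
      return(paste("nodes must have columns:", paste(req, collapse = ", ")))
    if (nrow(nd) == 0L) return("tree has no nodes")
    if (anyDuplicated(nd$id)) return("node ids are not unique")
    roots <- which(is.na(nd$parent))
    if (length(roots) != 1L) return("tree must have exactly one root node")
    if (nd$id[roots] != object@rootId) return("rootId does not match the parentless node")
    nonroot <- nd[-roots, , drop = FALSE]
    if (nrow(nonroot) > 0L) {
      pidx <- match(nonroot$parent, nd$id)
      if (anyNA(pidx)) return("some nodes reference a missing parent id")
      seg <- sqrt((nonroot$x - nd$x[pidx])^2 + (nonroot$y - nd$y[pidx])^2 +
                  (nonroot$z - nd$z[pidx])^2)
      if (!all(is.finite(seg)) || any(seg <= 0))
        return("all segment lengths must be finite and > 0")
      # acyclicity: walk each node towards the root, memoising visited nodes
      ord <- match(nd$parent, nd$id)
      n <- nrow(nd)
      good <- is.na(ord)
      for (i in seq_len(n)) {
        if (good[i]) next
        path <- integer(0)
        j <- i
        while (!good[j]) {
          if (j %in% path) return("parent chain contains a cycle")
          path <- c(path, j)
          j <- ord[j]
        }
        good[path] <- TRUE
      }
    }
    if (any(nd$radius < 0)) return("radii must be >= 0")
    TRUE
  }
)

#' ShollCurve: intersection counts on concentric shells
#'
#' Counts of process intersections with concentric circles (2D) or spheres
#' (3D) centred on the soma, at radii `k * step` for `k = 1, 2, ...`.
#'
#' @slot step shell spacing Delta-r in micrometres (> 0).
#' @slot radii numeric vector of radii, strictly increasing, starting at
#'   `step`.
#' @slot counts integer vector of intersection counts, same length as
#'   `radii`; zero beyond the farthest node.
#' @slot dimension 2L or 3L: whether counts are circle or sphere crossings.
#'
#' @export
setClass("ShollCurve",
  representation(step = "numeric", radii = "numeric", counts = "integer",
                 dimension = "integer"),
  validity = function(object) {
    if (length(object@step) != 1L || object@step <= 0) return("step must be > 0")
    if (length(object@radii) != length(object@counts))
      return("radii and counts must have the same length")
    if (length(object@radii) > 0) {
      if (any(diff(object@radii) <= 0)) return("radii must be strictly increasing")
      if (abs(object@radii[1L] - object@step) > 1e-9) return("radii must start at step")
    }
    if (any(object@counts < 0)) return("counts must be non-negative")
    if (!object@dimension %in% c(2L, 3L)) return("dimension must be 2 or 3")
    TRUE
  }
)

#' ImageStack: intensity image plus physical voxel dimensions
#'
#' A 2D image or 3D stack of non-negative intensities with its voxel (pixel)
#' size in micrometres. 3D arrays are indexed `[y, x, z]`, 2D `[y, x]`.
#'
#' @slot data numeric array (2D or 3D) of finite intensities.
#' @slot voxelSize named numeric vector `c(z=, y=, x=)` in micrometres, all
#'   components > 0 (`z` is ignored for 2D data).
#' @slot channel character label (e.g. "pre", "post", "astro").
#'
#' @export
setClass("ImageStack",
  representation(data = "array", voxelSize = "numeric", channel = "character"),
  validity = function(object) {
    nd <- length(dim(object@data))
    if (!nd %in% c(2L, 3L)) return("data must be a 2D or 3D array")
    if (!all(is.finite(object@data))) return("data must be finite")
    vs <- object@voxelSize
    if (!all(c("z", "y", "x") %in% names(vs)))
      return("voxelSize must be a named vector with z, y, x components")
    if (any(vs <= 0)) return("voxelSize components must be > 0")
    TRUE
  }
)

#' PunctaSet: labelled connected components of a thresholded channel
#'
#' @slot labels integer array, same shape as the source mask; background 0,
#'   puncta labelled with consecutive positive integers.
#' @slot sizes integer vector: pixel (voxel) count per label.
#' @slot minSize minimum component size (pixels) that was applied.
#'
#' @export
setClass("PunctaSet",
  representation(labels = "array", sizes = "integer", minSize = "integer"),
  validity = function(object) {
    n <- length(object@sizes)
    if (n > 0L) {
      lab <- sort(unique(as.integer(object@labels[object@labels > 0L])))
      if (!identical(lab, seq_len(n)))
        return("labels must be consecutive positive integers starting at 1")
      if (any(object@sizes < object@minSize))
        return("every component must have size >= minSize")
    } else if (any(object@labels > 0L)) {
      return("sizes is empty but labels has foreground")
    }
    TRUE
  }
)

#' StudyDesign: the FISH sampling layout
#'
#' Layers by timepoints by animals by sections; one image per cell of the
#' design. The default mirrors a developmental-cortex FISH study: five
#' cortical layers, four timepoints, three animals per timepoint, three
#' sections per animal (180 images).
#'
#' @slot layers character vector of cortical layers.
#' @slot timepoints character vector of developmental timepoints.
#' @slot animalsPerTimepoint integer.
#' @slot sectionsPerAnimal integer.
#'
#' @export
setClass("StudyDesign",
  representation(layers = "character", timepoints = "character",
                 animalsPerTimepoint = "integer", sectionsPerAnimal = "integer"),
  validity = function(object) {
    if (length(object@layers) < 1L || length(object@timepoints) < 1L)
      return("layers and timepoints must be non-empty")
    if (object@animalsPerTimepoint < 1L || object@sectionsPerAnimal < 1L)
      return("animalsPerTimepoint and sectionsPerAnimal must be >= 1")
    TRUE
  }
)

setMethod("show", "FilamentTree", function(object) {
  nd <- object@nodes
  cat("FilamentTree with", nrow(nd), "nodes (root id", object@rootId, ")\n")
  cat("  total branch length:", round(totalBranchLength(object), 2), "um\n")
})

setMethod("show", "ShollCurve", function(object) {
  cat("ShollCurve (", object@dimension, "D, step ", object@step, " um, ",
      length(object@radii), " shells)\n", sep = "")
  pk <- peakOfCurve(object)
  cat("  peak:", pk["peak_count"], "intersections at r =", pk["peak_radius"], "um\n")
})

setMethod("show", "ImageStack", function(object) {
  cat("ImageStack [", paste(dim(object@data), collapse = " x "), "] channel '",
      object@channel, "', voxel ", paste(signif(object@voxelSize, 3), collapse = "/"),
      " um (z/y/x)\n", sep = "")
})

setMethod("show", "PunctaSet", function(object) {
  cat("PunctaSet with", length(object@sizes), "puncta (minSize",
      object@minSize, "px)\n")
})

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", length(object@layers), "layers x",
      length(object@timepoints), "timepoints x",
      object@animalsPerTimepoint, "animals x",
      object@sectionsPerAnimal, "sections =", designSize(object), "images\n")
})
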