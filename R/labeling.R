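# Connected-component labelling on binary masks via the foreground-voxel
# adjacency graph (igraph). 2D masks use 8-connectivity, 3D masks use
# 26-connectivity; component counts depend on this choice, so it is fixed
# here rather than configurable per call.

neighborOffsets <- function(ndim) {
  if (ndim == 2L) {
    g <- expand.grid(dy = -1:1, dx = -1:1)
    g$dz <- 0L
  } else {
    g <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  }
  g <- g[!(g$dy == 0L & g$dx == 0L & g$dz == 0L), ]
  # half neighbourhood: each undirected adjacency appears once
  keep <- g$dz > 0L | (g$dz == 0L & (g$dx > 0L | (g$dx == 0L & g$dy > 0L)))
  as.matrix(g[keep, c("dy", "dx", "dz"), drop = FALSE])
}

#' Label connected components of a binary mask
#'
#' 8-connectivity for 2D masks, 26-connectivity for 3D masks.
#'
#' @param mask logical/0-1 array (2D or 3D).
#' @return integer array of the same shape: background 0, components
#'   labelled 1..n in order of their first (column-major) pixel.
#' @export
labelComponents <- function(mask) {
  d <- dim(mask)
  if (is.null(d) || !length(d) %in% c(2L, 3L))
    stop("mask must be a 2D or 3D array")
  ndim <- length(d)
  fg <- which(mask > 0)
  lab <- array(0L, dim = d)
  if (length(fg) == 0L) return(lab)
  d3 <- if (ndim == 2L) c(d, 1L) else d
  ai <- arrayInd(fg, d3)
  off <- neighborOffsets(ndim)
  from <- integer(0); to <- integer(0)
  pos <- rep(NA_integer_, prod(d3))
  pos[fg] <- seq_along(fg)
  for (k in seq_len(nrow(off))) {
    yy <- ai[, 1L] + off[k, 1L]
    xx <- ai[, 2L] + off[k, 2L]
    zz <- ai[, 3L] + off[k, 3L]
    ok <- yy >= 1L & yy <= d3[1L] & xx >= 1L & xx <= d3[2L] &
          zz >= 1L & zz <= d3[3L]
    if (!any(ok)) next
    nb <- pos[(zz[ok] - 1L) * d3[1L] * d3[2L] + (xx[ok] - 1L) * d3[1L] + yy[ok]]
    hit <- !is.na(nb)
    from <- c(from, which(ok)[hit])
    to <- c(to, nb[hit])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # relabel so that component 1 is the one containing the first foreground
  # pixel in column-major order, etc.
  first <- tapply(seq_along(fg), comp, min)
  newId <- integer(max(comp))
  newId[as.integer(names(first))[order(first)]] <- seq_along(first)
  lab[fg] <- newId[comp]
  lab
}

#' Detect puncta as size-filtered connected components
#'
#' Labels connected components of a thresholded channel (8-connectivity in
#' 2D, 26 in 3D), removes components smaller than `minSize` pixels and
#' compacts the remaining labels to 1..n.
#'
#' @param mask logical/0-1 array.
#' @param minSize minimum component size in pixels (default 4, small-object
#'   removal).
#' @return a [PunctaSet-class].
#' @export
findPuncta <- function(mask, minSize = 4L) {
  lab <- labelComponents(mask)
  n0 <- max(lab)
  if (n0 == 0L)
    return(new("PunctaSet", labels = lab, sizes = integer(0),
               minSize = as.integer(minSize)))
  sizes <- tabulate(lab[lab > 0L], nbins = n0)
  keep <- which(sizes >= minSize)
  remap <- integer(n0)
  remap[keep] <- seq_along(keep)
  out <- array(0L, dim = dim(lab))
  fg <- lab > 0L
  out[fg] <- remap[lab[fg]]
  new("PunctaSet", labels = out, sizes = as.integer(sizes[keep]),
      minSize = as.integer(minSize))
}

#' Centroids of puncta
#'
#' @param puncta a [PunctaSet-class].
#' @return matrix with one row per punctum, columns are the centroid array
#'   indices: y, x and (for 3D masks) z.
#' @export
punctaCentroids <- function(puncta) {
  lab <- punctaLabels(puncta)
  n <- punctaCount(puncta)
  d <- dim(lab)
  if (n == 0L) return(matrix(numeric(0), 0L, length(d)))
  fg <- which(lab > 0L)
  ai <- arrayInd(fg, d)
  t(vapply(seq_len(n), function(i)
    colMeans(ai[lab[fg] == i, , drop = FALSE]), numeric(length(d))))
}
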