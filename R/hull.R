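# 3D convex hull volume via incremental (quickhull-style) insertion.
# Pure R; point sets here are filament reconstructions (<= a few thousand
# nodes), for which the vectorised visibility test is fast enough.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Volume of the convex hull of a 3D point cloud
#'
#' @param pts numeric matrix with 3 columns (micrometres).
#' @return hull volume. Errors on degenerate geometry (< 4 distinct points,
#'   or all points collinear/coplanar).
#' @export
convexHullVolume3d <- function(pts) {
  convexHull3d(pts)$volume
}

#' Convex hull of a 3D point cloud
#'
#' Incremental construction. Returns the triangulated boundary with
#' outward unit normals, so that a point `p` is inside the hull iff
#' `normals %*% p <= offsets` for every facet.
#'
#' @param pts numeric matrix with 3 columns.
#' @return list: `volume`, `faces` (m x 3 indices into the de-duplicated
#'   point set), `normals` (m x 3 outward unit normals), `offsets`
#'   (length m), `points` (the de-duplicated point matrix).
#' @export
convexHull3d <- function(pts) {
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) stop("pts must have 3 columns")
  if (!all(is.finite(pts))) stop("pts must be finite")
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 4L) stop("degenerate geometry: need >= 4 distinct points for a 3D hull")
  scale <- max(apply(pts, 2L, function(v) diff(range(v))))
  if (scale <= 0) stop("degenerate geometry: all points identical")
  eps <- 1e-9 * scale

  # --- initial tetrahedron ---------------------------------------------
  i1 <- which.min(pts[, 1L])
  w <- sweep(pts, 2L, pts[i1, ])
  i2 <- which.max(rowSums(w^2))
  v12 <- pts[i2, ] - pts[i1, ]
  l12 <- sqrt(sum(v12^2))
  if (l12 <= eps) stop("degenerate geometry: all points identical")
  cr <- cbind(w[, 2L] * v12[3L] - w[, 3L] * v12[2L],
              w[, 3L] * v12[1L] - w[, 1L] * v12[3L],
              w[, 1L] * v12[2L] - w[, 2L] * v12[1L])
  i3 <- which.max(rowSums(cr^2))
  if (sqrt(sum(cr[i3, ]^2)) / l12 <= eps)
    stop("degenerate geometry: points are collinear")
  n0 <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  n0 <- n0 / sqrt(sum(n0^2))
  dplane <- abs(drop(w %*% n0))
  i4 <- which.max(dplane)
  if (dplane[i4] <= eps)
    stop("degenerate geometry: all points are coplanar")

  inner <- colMeans(pts[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient <- function(f) {
    a <- pts[f[1L], ]
    nrm <- cross3(pts[f[2L], ] - a, pts[f[3L], ] - a)
    ln <- sqrt(sum(nrm^2))
    # near-zero-area face (apex almost on the horizon edge): orient it
    # radially so it stays invisible and contributes ~0 volume
    if (ln <= 1e-14 * scale^2) { nrm <- a - inner; ln <- sqrt(sum(nrm^2)) }
    nrm <- nrm / ln
    if (sum(nrm * (inner - a)) > 0) { f <- f[c(1L, 3L, 2L)]; nrm <- -nrm }
    list(f = f, nrm = nrm, off = sum(nrm * pts[f[1L], ]))
  }
  o <- lapply(seq_len(4L), function(k) orient(faces[k, ]))
  faces <- do.call(rbind, lapply(o, `[[`, "f"))
  normals <- do.call(rbind, lapply(o, `[[`, "nrm"))
  offs <- vapply(o, `[[`, numeric(1L), "off")

  # --- incremental insertion -------------------------------------------
  for (i in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    p <- pts[i, ]
    dist <- drop(normals %*% p) - offs
    vis <- dist > eps
    if (!any(vis)) next
    visFaces <- faces[vis, , drop = FALSE]
    # horizon: directed edges of visible faces whose undirected partner
    # appears only once within the visible set
    e <- rbind(visFaces[, c(1L, 2L)], visFaces[, c(2L, 3L)], visFaces[, c(3L, 1L)])
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    horizon <- e[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    newo <- lapply(seq_len(nrow(horizon)), function(k)
      orient(c(horizon[k, ], i)))
    faces <- rbind(faces[!vis, , drop = FALSE],
                   do.call(rbind, lapply(newo, `[[`, "f")))
    normals <- rbind(normals[!vis, , drop = FALSE],
                     do.call(rbind, lapply(newo, `[[`, "nrm")))
    offs <- c(offs[!vis], vapply(newo, `[[`, numeric(1L), "off"))
  }

  # --- volume -----------------------------------------------------------
  a <- pts[faces[, 1L], , drop = FALSE]
  b <- pts[faces[, 2L], , drop = FALSE]
  cc <- pts[faces[, 3L], , drop = FALSE]
  a <- sweep(a, 2L, inner); b <- sweep(b, 2L, inner); cc <- sweep(cc, 2L, inner)
  dets <- a[, 1L] * (b[, 2L] * cc[, 3L] - b[, 3L] * cc[, 2L]) -
          a[, 2L] * (b[, 1L] * cc[, 3L] - b[, 3L] * cc[, 1L]) +
          a[, 3L] * (b[, 1L] * cc[, 2L] - b[, 2L] * cc[, 1L])
  list(volume = sum(abs(dets)) / 6, faces = faces, normals = normals,
       offsets = offs, points = pts)
}
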