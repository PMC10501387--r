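# Small array-processing helpers for 3D stacks. EBImage covers the 2D
# cases; these are the 3D (anisotropic-voxel) equivalents.

# separable Gaussian convolution; sigma in voxels per array dimension,
# edges renormalised (truncated-kernel normalisation)
gaussianSmooth <- function(arr, sigmaVox) {
  d <- dim(arr)
  stopifnot(length(sigmaVox) == length(d))
  for (ax in seq_along(d)) {
    s <- sigmaVox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    n <- d[ax]
    # banded convolution matrix with edge renormalisation
    K <- matrix(0, n, n)
    for (j in seq(-r, r)) {
      idx <- seq_len(n)
      ok <- idx + j >= 1L & idx + j <= n
      K[cbind(idx[ok], idx[ok] + j)] <- k[j + r + 1L]
    }
    K <- K / rowSums(K)
    perm <- c(ax, seq_along(d)[-ax])
    a <- aperm(arr, perm)
    dimA <- dim(a)
    a <- K %*% matrix(a, nrow = n)
    dim(a) <- dimA
    arr <- aperm(a, order(perm))
  }
  arr
}

# binary dilation/erosion with a 1-voxel (3^ndim) structuring element
shiftPad <- function(arr, sh, fill) {
  d <- dim(arr)
  out <- array(fill, dim = d)
  dst <- lapply(seq_along(d), function(ax) {
    i <- seq_len(d[ax])
    i[i - sh[ax] >= 1L & i - sh[ax] <= d[ax]]
  })
  if (any(lengths(dst) == 0L)) return(out)
  src <- lapply(seq_along(d), function(ax) dst[[ax]] - sh[ax])
  block <- do.call(`[`, c(list(arr), src, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), dst, list(value = block)))
}

binaryMorph <- function(mask, op = c("dilate", "erode")) {
  op <- match.arg(op)
  d <- dim(mask)
  fill <- op == "erode"
  acc <- mask
  shifts <- as.matrix(do.call(expand.grid, rep(list(-1:1), length(d))))
  shifts <- shifts[rowSums(abs(shifts)) > 0L, , drop = FALSE]
  for (i in seq_len(nrow(shifts))) {
    sh <- shifts[i, ]
    s <- shiftPad(mask, sh, fill)
    acc <- if (op == "dilate") acc | s else acc & s
  }
  acc
}

# dilation then erosion
binaryClose <- function(mask) binaryMorph(binaryMorph(mask, "dilate"), "erode")

# 1-voxel closing applied within each z slice. For anisotropic stacks a
# cube structuring element is physically lopsided (the z step is several
# times the lateral spacing) and inflates truncated blobs at the stack
# faces, so the closing acts in-plane only.
binaryCloseInPlane <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) return(binaryClose(mask))
  for (k in seq_len(d[3L])) mask[, , k] <- binaryClose(mask[, , k])
  mask
}
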