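# Excitatory-synapse quantification: substack z-projection, per-channel
# thresholding, puncta detection (labeling.R) and pixel-based pre/post
# colocalization, with density normalized to the astrocyte area.

#' Split a z-stack into substacks and maximum-project each
#'
#' Divides the stack into consecutive groups of
#' `round(substackThickness / z_step)` slices and max-projects each group
#' along z. A trailing incomplete group is dropped with a warning.
#'
#' @param stack a 3D [ImageStack-class].
#' @param substackThickness physical substack thickness in micrometres
#'   (default 1.02); must be an integer multiple of the z step (to 1e-6).
#' @return list of 2D [ImageStack-class] projections.
#' @export
splitAndProject <- function(stack, substackThickness = 1.02) {
  dat <- stackData(stack)
  if (length(dim(dat)) != 3L) stop("stack must be 3D")
  zstep <- voxelSize(stack)[["z"]]
  k <- substackThickness / zstep
  if (abs(k - round(k)) > 1e-6)
    stop("substackThickness is not a multiple of the z step; residue = ",
         signif(abs(k - round(k)) * zstep, 4), " um")
  k <- as.integer(round(k))
  nz <- dim(dat)[3L]
  ng <- nz %/% k
  if (ng == 0L) stop("stack has fewer slices than one substack")
  if (nz %% k != 0L)
    warning("dropping ", nz %% k, " trailing slice(s) not filling a substack")
  lapply(seq_len(ng), function(g) {
    sl <- dat[, , ((g - 1L) * k + 1L):(g * k), drop = FALSE]
    proj <- apply(sl, c(1L, 2L), max)
    imageStack(proj, voxelSize(stack), channel = stack@channel)
  })
}

#' Threshold a channel
#'
#' @param image an [ImageStack-class] or numeric array.
#' @param method `"fixed"` (threshold = `value`), `"percentile"`
#'   (threshold = the `value`-th percentile of intensities, `value` in
#'   (0, 100)) or `"otsu"`.
#' @param value intensity for `"fixed"`, percentile for `"percentile"`,
#'   ignored for `"otsu"`.
#' @return logical mask (`image > threshold`) with the resolved numeric
#'   threshold in `attr(, "threshold")`.
#' @export
thresholdChannel <- function(image, method = c("percentile", "fixed", "otsu"),
                             value = NULL) {
  method <- match.arg(method)
  dat <- if (is(image, "ImageStack")) stackData(image) else image
  thr <- switch(method,
    fixed = {
      if (is.null(value)) stop("method 'fixed' requires a threshold value")
      value
    },
    percentile = {
      if (is.null(value) || value <= 0 || value >= 100)
        stop("method 'percentile' requires a value in (0, 100)")
      as.numeric(quantile(dat, value / 100, names = FALSE))
    },
    otsu = {
      rg <- range(dat)
      if (rg[1L] == rg[2L]) {
        warning("constant image: Otsu threshold degenerate, empty mask")
        rg[2L]
      } else {
        # single global threshold over all voxels
        EBImage::otsu(matrix(as.numeric(dat), ncol = 1L), range = rg)
      }
    })
  mask <- dat > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Colocalize pre- and post-synaptic puncta
#'
#' Pixel-based colocalization: a pre-channel punctum is colocalized when it
#' shares at least one pixel with any post-channel punctum. The default
#' counting unit is the number of such pre puncta (a pre punctum touching
#' two post puncta counts once); `mode = "union"` instead counts connected
#' components of the pre/post overlap region.
#'
#' @param pre,post [PunctaSet-class] objects on the same image shape.
#' @param mode `"pre"` (default) or `"union"`.
#' @return list with `n_coloc` (integer) and `pairs` (data.frame
#'   `pre_label`, `post_label`, `n_pixels` for every overlapping pair).
#' @export
colocalizePuncta <- function(pre, post, mode = c("pre", "union")) {
  mode <- match.arg(mode)
  lp <- punctaLabels(pre); lq <- punctaLabels(post)
  if (!identical(dim(lp), dim(lq)))
    stop("pre and post puncta sets have different image shapes")
  both <- lp > 0L & lq > 0L
  if (!any(both)) {
    pairs <- data.frame(pre_label = integer(0), post_label = integer(0),
                        n_pixels = integer(0))
    return(list(n_coloc = 0L, pairs = pairs))
  }
  tab <- table(pre_label = lp[both], post_label = lq[both])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0L, ]
  pairs <- data.frame(pre_label = as.integer(df$pre_label),
                      post_label = as.integer(df$post_label),
                      n_pixels = as.integer(df$Freq))
  pairs <- pairs[order(pairs$pre_label, pairs$post_label), ]
  rownames(pairs) <- NULL
  n <- switch(mode,
    pre = length(unique(pairs$pre_label)),
    union = max(labelComponents(both)))
  list(n_coloc = as.integer(n), pairs = pairs)
}

#' Synaptic density within the astrocyte
#'
#' Density of colocalized synaptic puncta normalized to the astrocyte
#' area: `n_coloc / (pixelArea * |astroMask|)`.
#'
#' @param nColoc integer count of colocalized puncta (already restricted
#'   to puncta whose pre-punctum centroid lies inside `astroMask`).
#' @param astroMask non-empty logical mask of the astrocyte.
#' @param pixelArea area of one pixel in square micrometres.
#' @param substackIndex optional substack number recorded in the result.
#' @return data.frame row: `substack`, `n_coloc`, `astro_area_um2`,
#'   `density_per_um2`.
#' @export
synapseDensity <- function(nColoc, astroMask, pixelArea, substackIndex = NA_integer_) {
  npix <- sum(astroMask > 0)
  if (npix == 0L) stop("astrocyte mask is empty")
  area <- npix * pixelArea
  data.frame(substack = substackIndex, n_coloc = as.integer(nColoc),
             astro_area_um2 = area, density_per_um2 = nColoc / area)
}

#' Quantify synapses in one three-channel stack
#'
#' Full per-image procedure: split the pre- and post-synaptic channels
#' into substacks and max-project each; threshold each projection; detect
#' puncta; restrict to pre puncta whose centroid lies inside the astrocyte
#' mask; colocalize; normalize to astrocyte area.
#'
#' @param pre,post 3D [ImageStack-class] of the pre- and post-synaptic
#'   channels.
#' @param astroMask 2D logical mask of the astrocyte (projected), or a 3D
#'   mask which is max-projected.
#' @param substackThickness micrometres (default 1.02).
#' @param threshold list with `method` and `value` passed to
#'   [thresholdChannel()] per channel (default 99th percentile).
#' @param minSize minimum punctum size in pixels.
#' @param mode colocalization counting unit, see [colocalizePuncta()].
#' @return data.frame with one row per substack (columns `substack`,
#'   `n_pre`, `n_post`, `n_coloc`, `astro_area_um2`, `density_per_um2`,
#'   `thr_pre`, `thr_post`).
#' @export
quantifySynapses <- function(pre, post, astroMask,
                             substackThickness = 1.02,
                             threshold = list(method = "percentile", value = 99),
                             minSize = 4L, mode = "pre") {
  stopifnot(identical(dim(stackData(pre)), dim(stackData(post))))
  if (is(astroMask, "ImageStack")) astroMask <- stackData(astroMask)
  if (length(dim(astroMask)) == 3L) astroMask <- apply(astroMask, c(1L, 2L), max)
  astroMask <- astroMask > 0
  pixelArea <- voxelSize(pre)[["y"]] * voxelSize(pre)[["x"]]
  pp <- splitAndProject(pre, substackThickness)
  qq <- splitAndProject(post, substackThickness)
  rows <- lapply(seq_along(pp), function(i) {
    mpre <- thresholdChannel(pp[[i]], threshold$method, threshold$value)
    mpost <- thresholdChannel(qq[[i]], threshold$method, threshold$value)
    sPre <- findPuncta(mpre, minSize)
    sPost <- findPuncta(mpost, minSize)
    # keep pre puncta whose centroid falls inside the astrocyte
    sPreIn <- restrictToMask(sPre, astroMask)
    cl <- colocalizePuncta(sPreIn, sPost, mode = mode)
    out <- synapseDensity(cl$n_coloc, astroMask, pixelArea, substackIndex = i)
    out$n_pre <- punctaCount(sPre)
    out$n_post <- punctaCount(sPost)
    out$thr_pre <- attr(mpre, "threshold")
    out$thr_post <- attr(mpost, "threshold")
    out
  })
  do.call(rbind, rows)
}

# drop puncta whose centroid lies outside `mask`, compacting labels
restrictToMask <- function(puncta, mask) {
  n <- punctaCount(puncta)
  if (n == 0L) return(puncta)
  ctr <- round(punctaCentroids(puncta))
  d <- dim(mask)
  inMask <- vapply(seq_len(n), function(i) {
    iy <- min(max(ctr[i, 1L], 1L), d[1L])
    ix <- min(max(ctr[i, 2L], 1L), d[2L])
    mask[iy, ix] > 0
  }, logical(1L))
  keep <- which(inMask)
  lab <- punctaLabels(puncta)
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  out <- array(0L, dim = dim(lab))
  fg <- lab > 0L
  out[fg] <- remap[lab[fg]]
  new("PunctaSet", labels = out,
      sizes = punctaSizes(puncta)[keep], minSize = puncta@minSize)
}
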