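# RNA-FISH quantification: soma segmentation from the reporter channel,
# mRNA puncta volume inside the soma, cell-type assignment of puncta by
# marker colocalization, and the expression score E = V_mRNA / V_soma.

#' Segment the astrocyte soma from a reporter channel
#'
#' Gaussian smoothing (physical sigma converted to voxels per axis),
#' thresholding, 1-voxel morphological closing, then keep the largest
#' connected component.
#'
#' @param reporter a 3D [ImageStack-class] of the soma reporter channel.
#' @param smoothSigma smoothing sigma in micrometres (default 0.3).
#' @param method `"otsu"` (default) or `"percentile"`.
#' @param value percentile for `method = "percentile"`.
#' @return list with `mask` (logical array), `v_soma` (soma volume, cubic
#'   micrometres) and `threshold` (resolved intensity threshold).
#' @export
segmentSoma <- function(reporter, smoothSigma = 0.3,
                        method = c("otsu", "percentile"), value = NULL) {
  method <- match.arg(method)
  dat <- stackData(reporter)
  if (length(dim(dat)) != 3L) stop("reporter must be a 3D stack")
  vs <- voxelSize(reporter)
  sigmaVox <- smoothSigma / c(vs[["y"]], vs[["x"]], vs[["z"]])
  sm <- gaussianSmooth(dat, sigmaVox)
  mask <- suppressWarnings(thresholdChannel(sm, method, value))
  thr <- attr(mask, "threshold")
  if (!any(mask)) stop("no soma detected: no foreground after threshold")
  mask <- binaryCloseInPlane(mask)
  lab <- labelComponents(mask)
  sizes <- tabulate(lab[lab > 0L])
  biggest <- which.max(sizes)
  mask <- lab == biggest
  list(mask = mask,
       v_soma = sizes[biggest] * voxelVolume(reporter),
       threshold = thr)
}

#' Volume of suprathreshold mRNA signal inside a mask
#'
#' @param mrna a 3D [ImageStack-class] of the mRNA probe channel.
#' @param threshold list with `method` and `value` for
#'   [thresholdChannel()], or a numeric fixed threshold.
#' @param restrictMask logical array, same shape as the stack (e.g. the
#'   soma mask); only voxels inside it are counted.
#' @return mRNA volume in cubic micrometres.
#' @export
mrnaPunctaVolume <- function(mrna, threshold, restrictMask) {
  dat <- stackData(mrna)
  if (!identical(dim(dat), dim(restrictMask)))
    stop("mrna stack and restrictMask have different shapes")
  mask <- if (is.numeric(threshold))
    thresholdChannel(mrna, "fixed", threshold)
  else
    thresholdChannel(mrna, threshold$method, threshold$value)
  sum(mask & restrictMask > 0) * voxelVolume(mrna)
}

#' Assign puncta to a cell type by marker colocalization
#'
#' A punctum is astrocytic when at least `minOverlapFrac` of its voxels
#' fall inside the astrocyte marker mask, neuronal when at least that
#' fraction falls inside the neuronal mask; puncta qualifying for both or
#' neither are `"unassigned"`.
#'
#' @param puncta a [PunctaSet-class].
#' @param astroMask,neuronMask logical arrays aligned with the puncta.
#' @param minOverlapFrac minimum voxel-overlap fraction (default 0.5).
#' @return character vector, one of `"astrocyte"`, `"neuron"`,
#'   `"unassigned"` per punctum.
#' @export
assignCellType <- function(puncta, astroMask, neuronMask, minOverlapFrac = 0.5) {
  lab <- punctaLabels(puncta)
  stopifnot(identical(dim(lab), dim(astroMask)),
            identical(dim(lab), dim(neuronMask)))
  n <- punctaCount(puncta)
  if (n == 0L) return(character(0))
  fg <- lab > 0L
  labs <- lab[fg]
  sizes <- punctaSizes(puncta)
  fracA <- tabulate(labs[astroMask[fg] > 0], nbins = n) / sizes
  fracN <- tabulate(labs[neuronMask[fg] > 0], nbins = n) / sizes
  isA <- fracA >= minOverlapFrac
  isN <- fracN >= minOverlapFrac
  out <- rep("unassigned", n)
  out[isA & !isN] <- "astrocyte"
  out[isN & !isA] <- "neuron"
  out
}

#' Expression score: mRNA volume normalized to soma volume
#'
#' @param vMrna mRNA puncta volume (cubic micrometres).
#' @param vSoma soma volume (cubic micrometres), > 0.
#' @return dimensionless expression score `vMrna / vSoma`.
#' @export
fishExpression <- function(vMrna, vSoma) {
  if (any(vSoma <= 0)) stop("soma volume must be > 0")
  vMrna / vSoma
}

#' Aggregate per-cell expression to animal- and group-level summaries
#'
#' Within each layer-by-timepoint stratum, cells are averaged per animal
#' first; the group summary is the mean and SEM over those animal means
#' (SEM is `NA` for a single animal).
#'
#' @param cells data.frame with columns `expression`, `animal`, `layer`,
#'   `timepoint` (one row per cell).
#' @return list with `animal` (animal-level means per stratum) and
#'   `group` (stratum-level mean, SEM and n_animals).
#' @export
aggregateExpression <- function(cells) {
  req <- c("expression", "animal", "layer", "timepoint")
  miss <- setdiff(req, names(cells))
  if (length(miss) > 0L)
    stop("cells is missing column(s): ", paste(miss, collapse = ", "))
  an <- aggregate(expression ~ animal + layer + timepoint, data = cells,
                  FUN = mean)
  names(an)[names(an) == "expression"] <- "mean_expression"
  an$n_cells <- aggregate(expression ~ animal + layer + timepoint,
                          data = cells, FUN = length)$expression
  gr <- aggregate(mean_expression ~ layer + timepoint, data = an,
                  FUN = mean)
  names(gr)[names(gr) == "mean_expression"] <- "mean"
  sem <- aggregate(mean_expression ~ layer + timepoint, data = an,
                   FUN = function(v) if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_)
  gr$sem <- sem$mean_expression
  gr$n_animals <- aggregate(mean_expression ~ layer + timepoint, data = an,
                            FUN = length)$mean_expression
  # strata present in the design but with no cells are simply absent;
  # warn so incomplete designs are visible
  if (anyNA(gr$sem))
    warning("stratum with a single animal: SEM reported as NA")
  list(animal = an, group = gr)
}

#' Quantify one FISH image
#'
#' Segments the soma from the reporter channel, measures suprathreshold
#' mRNA volume inside the soma mask (optionally dilated) and returns the
#' expression score.
#'
#' @param reporter,mrna 3D [ImageStack-class] channels.
#' @param smoothSigma soma-segmentation smoothing sigma (micrometres).
#' @param mrnaThreshold threshold spec for the mRNA channel (numeric fixed
#'   value or list for [thresholdChannel()]).
#' @param dilateUm dilation radius applied to the soma mask before
#'   restricting mRNA voxels, micrometres (default 0: soma mask itself).
#' @return data.frame row: `v_soma_um3`, `v_mrna_um3`, `expression`.
#' @export
quantifyFishImage <- function(reporter, mrna, smoothSigma = 0.3,
                              mrnaThreshold = list(method = "otsu", value = NULL),
                              dilateUm = 0) {
  seg <- segmentSoma(reporter, smoothSigma)
  mask <- seg$mask
  if (dilateUm > 0) {
    nIter <- ceiling(dilateUm / min(voxelSize(reporter)))
    for (i in seq_len(nIter)) mask <- binaryMorph(mask, "dilate")
  }
  vm <- mrnaPunctaVolume(mrna, mrnaThreshold, mask)
  data.frame(v_soma_um3 = seg$v_soma, v_mrna_um3 = vm,
             expression = fishExpression(vm, seg$v_soma))
}
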