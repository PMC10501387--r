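# Synthetic three-channel synapse stacks and full FISH study datasets with
# known ground truth. Truth records travel next to the generated images and
# are never read by the measurement code.

# add a 3D Gaussian spot to `arr` (dims y,x,z); centre in physical um,
# sigma_xy/sigma_z in um
addSpot <- function(arr, centre, sigmaXY, sigmaZ, vs, amplitude = 1) {
  d <- dim(arr)
  cy <- centre[2L] / vs[["y"]]; cx <- centre[1L] / vs[["x"]]
  cz <- centre[3L] / vs[["z"]]
  ry <- ceiling(3 * sigmaXY / vs[["y"]]); rx <- ceiling(3 * sigmaXY / vs[["x"]])
  rz <- ceiling(3 * sigmaZ / vs[["z"]])
  iy <- max(1L, floor(cy - ry)):min(d[1L], ceiling(cy + ry))
  ix <- max(1L, floor(cx - rx)):min(d[2L], ceiling(cx + rx))
  iz <- max(1L, floor(cz - rz)):min(d[3L], ceiling(cz + rz))
  if (length(iy) == 0L || length(ix) == 0L || length(iz) == 0L) return(arr)
  gy <- exp(-((iy - 0.5) * vs[["y"]] - centre[2L])^2 / (2 * sigmaXY^2))
  gx <- exp(-((ix - 0.5) * vs[["x"]] - centre[1L])^2 / (2 * sigmaXY^2))
  gz <- exp(-((iz - 0.5) * vs[["z"]] - centre[3L])^2 / (2 * sigmaZ^2))
  spot <- amplitude * outer(outer(gy, gx), gz)
  arr[iy, ix, iz] <- pmax(arr[iy, ix, iz], spot)
  arr
}

#' Generate a synthetic three-channel synapse stack
#'
#' Places Poisson-distributed pre- and post-synaptic puncta as Gaussian
#' spots in a 3D field; a programmed fraction `colocFraction` of the pre
#' puncta receive a post partner within half a punctum radius, the
#' remaining post puncta are independent. Gaussian background noise is
#' added to both synaptic channels. The astrocyte channel carries the
#' supplied mask replicated over z.
#'
#' @param astroMask 2D logical/0-1 array (or [ImageStack-class]) defining
#'   the astrocyte footprint; also fixes the y/x field size.
#' @param preDensity,postDensity expected puncta per square micrometre of
#'   field (pre channel; independent post puncta).
#' @param colocFraction fraction of pre puncta given a post partner.
#' @param punctumRadius punctum radius in micrometres (rendered with
#'   lateral sigma `punctumRadius / 2`); must be at least one voxel.
#' @param noiseSd Gaussian background noise sd (spot amplitude is 1).
#' @param voxelSize named `c(z=,y=,x=)` micrometres.
#' @param nz number of z slices.
#' @param seed optional RNG seed (the stack is a pure function of its
#'   arguments and the seed).
#' @return list with `pre`, `post`, `astro` ([ImageStack-class]) and
#'   `truth` (list: `n_pre`, `n_post_independent`, `n_coloc_planted`,
#'   `n_coloc_in_astro`, planted centre coordinates).
#' @export
generateSynapseStack <- function(astroMask,
                                 preDensity = 0.12, postDensity = 0.12,
                                 colocFraction = 0.5,
                                 punctumRadius = 0.3, noiseSd = 0.05,
                                 voxelSize = c(z = 0.34, y = 0.1, x = 0.1),
                                 nz = 9L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is(astroMask, "ImageStack")) astroMask <- stackData(astroMask)
  stopifnot(length(dim(astroMask)) == 2L,
            colocFraction >= 0, colocFraction <= 1,
            preDensity >= 0, postDensity >= 0)
  if (is.null(names(voxelSize))) names(voxelSize) <- c("z", "y", "x")
  if (punctumRadius < max(voxelSize[c("y", "x")]))
    stop("punctum radius is smaller than one voxel")
  d <- c(dim(astroMask), nz)
  extY <- d[1L] * voxelSize[["y"]]; extX <- d[2L] * voxelSize[["x"]]
  extZ <- nz * voxelSize[["z"]]
  area <- extY * extX
  sigmaXY <- punctumRadius / 2
  sigmaZ <- punctumRadius / 2
  nPre <- rpois(1L, preDensity * area)
  nPostInd <- rpois(1L, postDensity * area)
  preC <- cbind(runif(nPre, 0, extX), runif(nPre, 0, extY), runif(nPre, 0, extZ))
  nCol <- round(colocFraction * nPre)
  partnerIdx <- if (nCol > 0L) seq_len(nCol) else integer(0)
  # partner within half a punctum radius of its pre punctum
  partC <- if (nCol > 0L) {
    u <- matrix(rnorm(3L * nCol), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    r <- (punctumRadius / 2) * runif(nCol)^(1 / 3)
    preC[partnerIdx, , drop = FALSE] + u * r
  } else matrix(numeric(0), 0L, 3L)
  postC <- rbind(partC,
                 cbind(runif(nPostInd, 0, extX), runif(nPostInd, 0, extY),
                       runif(nPostInd, 0, extZ)))
  mkChan <- function(centres, label) {
    arr <- array(0, dim = d)
    for (i in seq_len(nrow(centres)))
      arr <- addSpot(arr, centres[i, ], sigmaXY, sigmaZ, voxelSize)
    arr <- arr + rnorm(length(arr), 0, noiseSd)
    imageStack(pmax(arr, 0), voxelSize, channel = label)
  }
  pre <- mkChan(preC, "pre")
  post <- mkChan(postC, "post")
  astro <- imageStack(array(rep(as.numeric(astroMask > 0), nz), dim = d),
                      voxelSize, channel = "astro")
  inAstro <- function(centres) {
    if (nrow(centres) == 0L) return(logical(0))
    iy <- pmin(pmax(ceiling(centres[, 2L] / voxelSize[["y"]]), 1L), d[1L])
    ix <- pmin(pmax(ceiling(centres[, 1L] / voxelSize[["x"]]), 1L), d[2L])
    astroMask[cbind(iy, ix)] > 0
  }
  truth <- list(n_pre = nPre, n_post_independent = nPostInd,
                n_coloc_planted = nCol,
                n_coloc_in_astro = sum(inAstro(preC[partnerIdx, , drop = FALSE])),
                pre_centres = preC, post_centres = postC)
  list(pre = pre, post = post, astro = astro, truth = truth)
}

#' Default per-stratum expression map for the FISH generator
#'
#' Equal expression across cortical layers within each timepoint (the
#' layer-null structure) with a developmental decline by the third
#' postnatal week.
#'
#' @param design a [StudyDesign-class].
#' @return data.frame `layer`, `timepoint`, `expression`.
#' @export
defaultFishExpression <- function(design = studyDesign()) {
  tpLevels <- design@timepoints
  ev <- setNames(rep(0.05, length(tpLevels)), tpLevels)
  ev[names(ev) == "P1"] <- 0.06
  ev[names(ev) == "P21"] <- 0.035
  g <- expand.grid(layer = design@layers, timepoint = tpLevels,
                   stringsAsFactors = FALSE)
  g$expression <- unname(ev[g$timepoint])
  g
}

#' Generate a synthetic RNA-FISH dataset with known stratum expression
#'
#' One multi-channel stack per design cell (layer x section x animal x
#' timepoint): a spherical soma in the reporter channel, suprathreshold
#' mRNA voxels inside the soma totalling the cell's programmed expression
#' times its soma volume, and a neuronal-marker channel with off-soma
#' blobs. Cell-level expression is the stratum value times a
#' mean-preserving lognormal cell factor and a lognormal animal factor.
#'
#' @param design a [StudyDesign-class].
#' @param expression data.frame (`layer`, `timepoint`, `expression`) or a
#'   single number used for every stratum; must cover all strata.
#' @param noiseSdLog lognormal sd of the cell-level expression factor.
#' @param animalSdLog lognormal sd of the animal-level factor.
#' @param somaRadius soma radius in micrometres.
#' @param dims image dims `c(y, x, z)`.
#' @param voxelSize named voxel size, micrometres.
#' @param noiseSd additive Gaussian image noise sd.
#' @param render if `FALSE`, skip image synthesis and return only the
#'   manifest and truth table (used for fast simulation of the downstream
#'   statistics under the same noise model).
#' @param seed RNG seed; the dataset is a pure function of its arguments
#'   and the seed.
#' @return list with `images` (list of per-image channel lists `reporter`,
#'   `mrna`, `neuron`; `NULL` when `render = FALSE`), `manifest`
#'   (data.frame) and `truth` (data.frame with per-image programmed
#'   expression and soma volume).
#' @export
generateFishDataset <- function(design = studyDesign(),
                                expression = defaultFishExpression(design),
                                noiseSdLog = 0.1, animalSdLog = 0.05,
                                somaRadius = 4,
                                dims = c(56L, 56L, 6L),
                                voxelSize = c(z = 1, y = 0.25, x = 0.25),
                                noiseSd = 0.05,
                                render = TRUE, seed = 1L) {
  set.seed(seed)
  if (is.null(names(voxelSize))) names(voxelSize) <- c("z", "y", "x")
  man <- designManifest(design)
  if (is.numeric(expression) && length(expression) == 1L) {
    e <- as.numeric(expression)
    expression <- expand.grid(layer = design@layers,
                              timepoint = design@timepoints,
                              stringsAsFactors = FALSE)
    expression$expression <- e
  }
  stratKey <- function(l, t) paste(l, t, sep = "|")
  emap <- setNames(expression$expression,
                   stratKey(expression$layer, expression$timepoint))
  need <- unique(stratKey(man$layer, man$timepoint))
  miss <- setdiff(need, names(emap))
  if (length(miss) > 0L)
    stop("expression map is missing stratum/strata: ",
         paste(miss, collapse = ", "))
  animals <- unique(man$animal)
  animalFac <- setNames(exp(rnorm(length(animals), -animalSdLog^2 / 2,
                                  animalSdLog)), animals)
  n <- nrow(man)
  cellFac <- exp(rnorm(n, -noiseSdLog^2 / 2, noiseSdLog))
  eTrue <- unname(emap[stratKey(man$layer, man$timepoint)]) *
    animalFac[man$animal] * cellFac
  images <- vector("list", n)
  vSomaTrue <- numeric(n)
  vs <- voxelSize
  # voxel-centre coordinate grids (um)
  ycoord <- (seq_len(dims[1L]) - 0.5) * vs[["y"]]
  xcoord <- (seq_len(dims[2L]) - 0.5) * vs[["x"]]
  zcoord <- (seq_len(dims[3L]) - 0.5) * vs[["z"]]
  for (i in seq_len(n)) {
    centre <- c(x = dims[2L] * vs[["x"]] / 2 + runif(1, -0.5, 0.5),
                y = dims[1L] * vs[["y"]] / 2 + runif(1, -0.5, 0.5),
                z = dims[3L] * vs[["z"]] / 2)
    dist2 <- outer(outer((ycoord - centre["y"])^2, (xcoord - centre["x"])^2, `+`),
                   (zcoord - centre["z"])^2, `+`)
    soma <- dist2 <= somaRadius^2
    nSoma <- sum(soma)
    vSomaTrue[i] <- nSoma * vs[["z"]] * vs[["y"]] * vs[["x"]]
    nMrna <- round(eTrue[i] * nSoma)
    if (render) {
      reporter <- array(as.numeric(soma), dim = dims) +
        rnorm(prod(dims), 0, noiseSd)
      mrna <- array(rnorm(prod(dims), 0, noiseSd), dim = dims)
      if (nMrna > 0L)
        mrna[sample(which(soma), nMrna)] <- 1
      neuron <- array(rnorm(prod(dims), 0, noiseSd), dim = dims)
      corner <- c(x = 2, y = 2, z = centre[["z"]])
      neuron <- addSpot(neuron, corner, 1.2, 1.2, vs)
      images[[i]] <- list(
        reporter = imageStack(pmax(reporter, 0), vs, "reporter"),
        mrna = imageStack(pmax(mrna, 0), vs, "mrna"),
        neuron = imageStack(pmax(neuron, 0), vs, "neuron"))
    }
  }
  truth <- cbind(man, data.frame(expression_true = eTrue,
                                 v_soma_true = vSomaTrue))
  list(images = if (render) images else NULL, manifest = man, truth = truth)
}
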