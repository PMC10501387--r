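# Stochastic branching-arbor generator. Growth is a Galton-Watson-style
# process on branch orders: from the soma a drawn number of primary
# processes grow outward; after every traced segment (gamma-distributed
# length, direction = previous direction plus angular jitter) the branch
# either bifurcates into two daughters of the next order, terminates, or
# continues. Presets carry fixed, documented constants chosen so that the
# measured per-condition mean total branch length and peak Sholl counts
# match the condition means of the study the generator emulates.

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0, 0) else v / n
}

#' Per-condition generative parameters for synthetic astrocyte arbors
#'
#' Returns the fixed parameter set for one named condition preset. The
#' constants are part of the package's study conditions; they are not
#' re-fitted at run time.
#'
#' @param name one of `"control_coculture"`, `"knockdown"`, `"rescue"`,
#'   `"overexpression"`, `"monoculture"`, `"control_invivo"`,
#'   `"knockdown_invivo"`.
#' @param ... named overrides of individual parameters.
#' @return a `ConditionParams` list with elements:
#'   `nPrimaryBase`, `nPrimarySpread` (primary-process count is
#'   `nPrimaryBase + Binomial(nPrimarySpread, 0.5)`), `branchProb`
#'   (per-node bifurcation probability by branch order), `stopProb`
#'   (per-node termination probability by order), `lengthShape`,
#'   `lengthScale` (gamma parameters of traced segment length, um),
#'   `maxOrder`, `angleSpread` (radians of per-segment direction jitter),
#'   `branchAngle` (radians of daughter-direction jitter at bifurcations),
#'   `somaRadius` (um) and `presetName`.
#' @export
conditionPreset <- function(name = c("control_coculture", "knockdown",
                                     "rescue", "overexpression",
                                     "monoculture", "control_invivo",
                                     "knockdown_invivo"), ...) {
  name <- match.arg(name)
  base <- list(
    nPrimaryBase = 5L, nPrimarySpread = 2L,
    lengthShape = 4, lengthScale = 1.5,
    angleSpread = 0.25, branchAngle = 0.55, somaRadius = 4,
    maxSegments = 25L,
    presetName = name)
  p <- switch(name,
    control_coculture = utils::modifyList(base, list(
      maxOrder = 6L,
      lengthScale = 1.449973,
      branchProb = c(0.120, 0.120, 0.120, 0.110, 0.100, 0),
      stopProb   = c(0.004, 0.004, 0.005, 0.006, 0.010, 0.130))),
    rescue = utils::modifyList(base, list(
      maxOrder = 6L,
      lengthScale = 1.273244,
      branchProb = c(0.120, 0.120, 0.120, 0.110, 0.100, 0),
      stopProb   = c(0.004, 0.004, 0.005, 0.006, 0.010, 0.130))),
    overexpression = utils::modifyList(base, list(
      maxOrder = 6L,
      lengthScale = 1.383078,
      branchProb = c(0.120, 0.120, 0.120, 0.110, 0.100, 0),
      stopProb   = c(0.004, 0.004, 0.005, 0.006, 0.010, 0.130))),
    knockdown = utils::modifyList(base, list(
      nPrimaryBase = 4L, nPrimarySpread = 0L,
      maxOrder = 3L,
      lengthScale = 2.190984,
      branchProb = c(0.050, 0.040, 0),
      stopProb   = c(0.004, 0.005, 0))),
    monoculture = utils::modifyList(base, list(
      nPrimaryBase = 5L,
      maxOrder = 2L,
      lengthScale = 1.25,
      branchProb = c(0.080, 0),
      stopProb   = c(0.020, 0.080))),
    control_invivo = utils::modifyList(base, list(
      nPrimaryBase = 6L,
      maxOrder = 6L,
      lengthScale = 0.75,
      branchProb = c(0.150, 0.150, 0.140, 0.120, 0.100, 0),
      stopProb   = c(0.010, 0.010, 0.012, 0.015, 0.020, 0.200))),
    knockdown_invivo = utils::modifyList(base, list(
      nPrimaryBase = 4L,
      maxOrder = 3L,
      lengthScale = 0.75,
      branchProb = c(0.060, 0.050, 0),
      stopProb   = c(0.010, 0.012, 0.060))))
  p <- utils::modifyList(p, list(...))
  validateConditionParams(p)
  p
}

validateConditionParams <- function(p) {
  stopifnot(p$nPrimaryBase >= 0, p$nPrimarySpread >= 0,
            p$maxOrder >= 1L,
            length(p$branchProb) == p$maxOrder,
            length(p$stopProb) == p$maxOrder,
            all(p$branchProb >= 0 & p$branchProb <= 1),
            all(p$stopProb >= 0 & p$stopProb <= 1),
            all(p$branchProb + p$stopProb <= 1),
            p$lengthShape > 0, p$lengthScale > 0, p$maxSegments >= 1L,
            p$angleSpread >= 0, p$branchAngle >= 0, p$somaRadius > 0)
  invisible(TRUE)
}

#' Generate one synthetic astrocyte arbor
#'
#' @param params a `ConditionParams` list from [conditionPreset()].
#' @param seed optional integer; if given, `set.seed(seed)` is called so
#'   the tree is a pure function of `(params, seed)`. If `NULL` the
#'   current RNG stream is used (for batch generation).
#' @return `list(tree = FilamentTree, truth = list(...))`. The truth
#'   record carries the exact generated totals (`total_length`, `n_nodes`,
#'   `n_primary`) and is never consumed by the measurement code.
#' @export
generateAstrocyteTree <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validateConditionParams(params)
  for (attempt in seq_len(10L)) {
    res <- growArbor(params)
    if (!is.null(res)) return(res)
  }
  stop("degenerate (0-segment) tree after 10 attempts; check params")
}

growArbor <- function(p, maxNodes = 60000L) {
  cap <- 4096L
  x <- numeric(cap); y <- numeric(cap); z <- numeric(cap)
  rad <- numeric(cap); par <- integer(cap); typ <- integer(cap)
  x[1L] <- y[1L] <- z[1L] <- 0
  rad[1L] <- p$somaRadius; par[1L] <- NA_integer_; typ[1L] <- 1L
  n <- 1L
  totalLen <- 0
  nPrim <- p$nPrimaryBase +
    if (p$nPrimarySpread > 0L) rbinom(1L, p$nPrimarySpread, 0.5) else 0L
  if (nPrim == 0L) return(NULL)
  # branch stack: each entry (parent node index, direction, order)
  stack <- vector("list", nPrim)
  for (i in seq_len(nPrim)) {
    v <- normalize3(rnorm(3L))
    stack[[i]] <- list(parent = 1L, dir = v, order = 1L)
  }
  ns <- nPrim
  while (ns > 0L) {
    br <- stack[[ns]]; ns <- ns - 1L
    cur <- br$parent; dir <- br$dir; o <- br$order
    pos <- c(x[cur], y[cur], z[cur])
    nseg <- 0L
    repeat {
      len <- max(rgamma(1L, shape = p$lengthShape, scale = p$lengthScale), 0.05)
      dir <- normalize3(dir + p$angleSpread * rnorm(3L))
      pos <- pos + len * dir
      n <- n + 1L
      if (n > cap) {
        cap <- cap * 2L
        length(x) <- cap; length(y) <- cap; length(z) <- cap
        length(rad) <- cap; length(par) <- cap; length(typ) <- cap
      }
      if (n > maxNodes) stop("runaway growth: more than ", maxNodes, " nodes")
      x[n] <- pos[1L]; y[n] <- pos[2L]; z[n] <- pos[3L]
      rad[n] <- max(0.1, 0.25 * p$somaRadius * 0.8^o)
      par[n] <- cur; typ[n] <- 3L
      cur <- n
      totalLen <- totalLen + len
      nseg <- nseg + 1L
      u <- runif(1L)
      b <- if (o < p$maxOrder) p$branchProb[o] else 0
      # branches have bounded length: once the cap is hit the branch must
      # bifurcate (if it still can) or terminate
      if (nseg >= p$maxSegments && b <= 0) break
      if (u < b || (nseg >= p$maxSegments && b > 0)) {
        for (k in 1:2) {
          ns <- ns + 1L
          stack[[ns]] <- list(parent = cur,
                              dir = normalize3(dir + p$branchAngle * rnorm(3L)),
                              order = o + 1L)
        }
        break
      } else if (u < b + p$stopProb[o]) {
        break
      }
    }
  }
  if (n < 2L) return(NULL)
  nodes <- data.frame(id = seq_len(n), type = typ[seq_len(n)],
                      x = x[seq_len(n)], y = y[seq_len(n)], z = z[seq_len(n)],
                      radius = rad[seq_len(n)], parent = par[seq_len(n)])
  list(tree = filamentTree(nodes),
       truth = list(total_length = totalLen, n_nodes = n, n_primary = nPrim))
}

#' Generate a population of synthetic arbors from one preset
#'
#' Seeds the RNG once and draws `n` trees sequentially, so the whole
#' population is a pure function of `(params, n, seed)`.
#'
#' @param params `ConditionParams` list or preset name.
#' @param n number of trees.
#' @param seed integer seed.
#' @return list with elements `trees` (list of FilamentTree) and `truth`
#'   (data.frame of per-tree truth records).
#' @export
generateAstrocytePopulation <- function(params, n, seed) {
  if (is.character(params)) params <- conditionPreset(params)
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- generateAstrocyteTree(params)
  list(trees = lapply(out, `[[`, "tree"),
       truth = do.call(rbind, lapply(out, function(o)
         as.data.frame(o$truth))))
}

#' Rasterise a filament tree into a binary voxel mask
#'
#' Marks every voxel whose centre lies within a segment's radius of the
#' sampled segment path; the soma is rendered as a sphere of the root
#' radius. Used to build astrocyte-mask channels for synthetic image
#' stacks.
#'
#' @param tree a [FilamentTree-class].
#' @param voxelSize named `c(z=,y=,x=)` voxel size in micrometres.
#' @param dims integer dims of the output array as `c(y, x, z)`.
#' @param origin world coordinates (um) of the corner of voxel
#'   `[1, 1, 1]` as `c(x, y, z)`; default centres the root node in the
#'   volume.
#' @return an [ImageStack-class] whose data is a 0/1 mask.
#' @export
renderTreeMask <- function(tree, voxelSize, dims, origin = NULL) {
  if (is.null(names(voxelSize))) names(voxelSize) <- c("z", "y", "x")
  if (any(voxelSize <= 0)) stop("voxelSize components must be > 0")
  if (length(dims) != 3L || any(dims < 1L)) stop("dims must be c(y, x, z), all >= 1")
  nd <- treeNodes(tree)
  ridx <- match(rootId(tree), nd$id)
  ext <- c(x = dims[2L] * voxelSize[["x"]], y = dims[1L] * voxelSize[["y"]],
           z = dims[3L] * voxelSize[["z"]])
  if (is.null(origin))
    origin <- c(nd$x[ridx] - ext["x"] / 2, nd$y[ridx] - ext["y"] / 2,
                nd$z[ridx] - ext["z"] / 2)
  px <- nd$x - origin[1L]; py <- nd$y - origin[2L]; pz <- nd$z - origin[3L]
  over <- c(x = any(px < 0 | px > ext["x"]), y = any(py < 0 | py > ext["y"]),
            z = any(pz < 0 | pz > ext["z"]))
  if (any(over))
    stop("tree does not fit in dims at this voxel size; overflow on axis: ",
         paste(names(over)[over], collapse = ", "))
  step <- min(voxelSize) / 2
  # sample points along every parent-child segment
  nonroot <- which(!is.na(nd$parent))
  pidx <- match(nd$parent[nonroot], nd$id)
  samp <- vector("list", length(nonroot) + 1L)
  for (k in seq_along(nonroot)) {
    i <- nonroot[k]; j <- pidx[k]
    a <- c(px[j], py[j], pz[j]); b <- c(px[i], py[i], pz[i])
    L <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(L / step) + 1L))
    samp[[k]] <- cbind(a[1L] + t * (b[1L] - a[1L]),
                       a[2L] + t * (b[2L] - a[2L]),
                       a[3L] + t * (b[3L] - a[3L]),
                       nd$radius[i])
  }
  # soma sphere at the root
  samp[[length(nonroot) + 1L]] <- cbind(px[ridx], py[ridx], pz[ridx],
                                        nd$radius[ridx])
  S <- do.call(rbind, samp)
  mask <- array(0, dim = dims)
  vs <- c(voxelSize[["y"]], voxelSize[["x"]], voxelSize[["z"]])
  for (r in sort(unique(S[, 4L]))) {
    P <- S[S[, 4L] == r, , drop = FALSE]
    iy <- pmin(pmax(ceiling(P[, 2L] / vs[1L]), 1L), dims[1L])
    ix <- pmin(pmax(ceiling(P[, 1L] / vs[2L]), 1L), dims[2L])
    iz <- pmin(pmax(ceiling(P[, 3L] / vs[3L]), 1L), dims[3L])
    if (r <= min(vs) / 2) {
      mask[cbind(iy, ix, iz)] <- 1
    } else {
      oy <- seq(-floor(r / vs[1L]), floor(r / vs[1L]))
      ox <- seq(-floor(r / vs[2L]), floor(r / vs[2L]))
      oz <- seq(-floor(r / vs[3L]), floor(r / vs[3L]))
      ball <- as.matrix(expand.grid(oy = oy, ox = ox, oz = oz))
      keep <- (ball[, 1L] * vs[1L])^2 + (ball[, 2L] * vs[2L])^2 +
              (ball[, 3L] * vs[3L])^2 <= r^2
      ball <- ball[keep, , drop = FALSE]
      for (b in seq_len(nrow(ball))) {
        yy <- iy + ball[b, 1L]; xx <- ix + ball[b, 2L]; zz <- iz + ball[b, 3L]
        ok <- yy >= 1L & yy <= dims[1L] & xx >= 1L & xx <= dims[2L] &
              zz >= 1L & zz <= dims[3L]
        mask[cbind(yy[ok], xx[ok], zz[ok])] <- 1
      }
    }
  }
  imageStack(mask, voxelSize, channel = "astro")
}
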