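# Independent brute-force oracles and random-input builders used across
# the suite. These deliberately share no code with the package internals.

# random rooted tree: each new node attaches to a uniformly chosen existing
# node with an outward step, resampled so that the distance to the root is
# monotone along every segment (outward-growing traces; see the methods
# vignette for why the crossing count is only defined segment-monotonically)
randomMonotoneTree <- function(nNodes = 50, stepMean = 6) {
  x <- c(0); y <- c(0); z <- c(0); parent <- c(NA_integer_)
  for (i in 2:nNodes) {
    repeat {
      j <- sample.int(i - 1L, 1L)
      d <- rnorm(3)
      d <- d / sqrt(sum(d^2)) * rexp(1, 1 / stepMean)
      a <- c(x[j], y[j], z[j]); b <- a + d
      if (sum(d^2) < 1e-6) next
      tstar <- -sum(a * (b - a)) / sum((b - a)^2)
      if (tstar <= 0 || tstar >= 1) break   # monotone wrt root at origin
    }
    x[i] <- b[1]; y[i] <- b[2]; z[i] <- b[3]; parent[i] <- j
  }
  filamentTree(data.frame(id = seq_len(nNodes), x = x, y = y, z = z,
                          radius = 0.5, parent = parent))
}

# naive total length: explicit loop over parent-child pairs
oracleTotalLength <- function(tree) {
  nd <- treeNodes(tree)
  tot <- 0
  for (i in seq_len(nrow(nd))) {
    if (is.na(nd$parent[i])) next
    j <- which(nd$id == nd$parent[i])
    tot <- tot + sqrt((nd$x[i] - nd$x[j])^2 + (nd$y[i] - nd$y[j])^2 +
                      (nd$z[i] - nd$z[j])^2)
  }
  tot
}

# dense-resampling Sholl oracle: sample every segment at `ds` spacing and
# count sign changes of (distance - r) per shell
oracleSholl <- function(tree, step = 5, dimension = 3, ds = 0.01) {
  nd <- treeNodes(tree)
  ridx <- which(is.na(nd$parent))
  root <- c(nd$x[ridx], nd$y[ridx], if (dimension == 3) nd$z[ridx] else 0)
  distRoot <- function(p) sqrt(sum((p - root)^2))
  maxd <- 0
  segs <- list()
  for (i in seq_len(nrow(nd))) {
    if (is.na(nd$parent[i])) next
    j <- which(nd$id == nd$parent[i])
    a <- c(nd$x[j], nd$y[j], if (dimension == 3) nd$z[j] else 0)
    b <- c(nd$x[i], nd$y[i], if (dimension == 3) nd$z[i] else 0)
    segs[[length(segs) + 1L]] <- rbind(a, b)
    maxd <- max(maxd, distRoot(a), distRoot(b))
  }
  nshell <- floor(maxd / step) + 1L
  counts <- integer(nshell)
  for (sg in segs) {
    L <- sqrt(sum((sg[2, ] - sg[1, ])^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(L / ds) + 1L))
    p <- outer(t, sg[2, ] - sg[1, ]) + rep(sg[1, ], each = length(t))
    d <- sqrt(rowSums((p - rep(root, each = length(t)))^2))
    for (k in seq_len(nshell)) {
      r <- k * step
      below <- d < r
      counts[k] <- counts[k] + sum(below[-length(below)] != below[-1L])
    }
  }
  counts
}

# flood-fill component labelling (BFS), 8-connectivity 2D / 26 3D
oracleComponents <- function(mask) {
  d <- dim(mask); if (length(d) == 2L) { mask <- array(mask, c(d, 1L)); d <- dim(mask) }
  lab <- array(0L, d); cur <- 0L
  for (i0 in seq_len(d[1])) for (j0 in seq_len(d[2])) for (k0 in seq_len(d[3])) {
    if (mask[i0, j0, k0] <= 0 || lab[i0, j0, k0] > 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i0, j0, k0), 1L)
    lab[i0, j0, k0] <- cur
    while (nrow(queue) > 0L) {
      v <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        ii <- v[1] + di; jj <- v[2] + dj; kk <- v[3] + dk
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
        if (mask[ii, jj, kk] > 0 && lab[ii, jj, kk] == 0L) {
          lab[ii, jj, kk] <- cur
          queue <- rbind(queue, c(ii, jj, kk))
        }
      }
    }
  }
  lab
}

# all-pairs pixel-intersection colocalization count (per pre punctum)
oracleColoc <- function(labPre, labPost) {
  n <- 0L
  for (i in seq_len(max(labPre, 0L))) {
    hit <- FALSE
    for (j in seq_len(max(labPost, 0L))) {
      if (any(labPre == i & labPost == j)) { hit <- TRUE; break }
    }
    if (hit) n <- n + 1L
  }
  n
}
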