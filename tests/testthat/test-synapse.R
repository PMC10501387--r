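vs <- c(z = 0.34, y = 0.1, x = 0.1)

test_that("substack projection groups slices by physical thickness", {
  set.seed(1)
  dat <- array(runif(20 * 20 * 9), dim = c(20, 20, 9))
  st <- imageStack(dat, vs, "pre")
  pr <- splitAndProject(st, 1.02)
  expect_length(pr, 3L)
  expect_equal(stackData(pr[[2]]), apply(dat[, , 4:6], c(1, 2), max))
  # constant stack: projections equal the constant image
  cst <- imageStack(array(7, dim = c(4, 4, 9)), vs)
  expect_true(all(vapply(splitAndProject(cst, 1.02), function(p)
    all(stackData(p) == 7), logical(1))))
  # trailing incomplete group dropped with a warning
  st10 <- imageStack(array(runif(4 * 4 * 10), dim = c(4, 4, 10)), vs)
  expect_warning(pr10 <- splitAndProject(st10, 1.02), "dropping 1")
  expect_length(pr10, 3L)
  expect_error(splitAndProject(st, 0.5), "residue")
})

test_that("thresholding resolves fixed, percentile and otsu thresholds", {
  img <- imageStack(matrix(c(0, 10, 20, 30), 2, 2, byrow = TRUE), vs)
  m <- thresholdChannel(img, "fixed", 15)
  expect_equal(as.vector(m), c(FALSE, TRUE, FALSE, TRUE))  # column-major
  expect_equal(attr(m, "threshold"), 15)
  expect_error(thresholdChannel(img, "fixed"), "requires")
  expect_warning(m0 <- thresholdChannel(imageStack(matrix(0, 5, 5), vs), "otsu"),
                 "constant")
  expect_false(any(m0))
  set.seed(2)
  big <- matrix(runif(1e4), 100)
  mp <- thresholdChannel(imageStack(big, vs), "percentile", 99)
  expect_equal(mean(mp), 0.01, tolerance = 0.05)
})

test_that("puncta detection matches the flood-fill oracle and size filter", {
  m <- matrix(0, 12, 12)
  m[2:4, 2:4] <- 1; m[8:10, 8:10] <- 1
  expect_equal(punctaCount(findPuncta(m, 4)), 2L)
  m2 <- matrix(0, 6, 6); m2[1, 1:3] <- 1
  expect_equal(punctaCount(findPuncta(m2, 4)), 0L)  # 3 px < minSize
  set.seed(3)
  for (rep in 1:5) {
    rm2 <- matrix(rbinom(400, 1, 0.3), 20)
    ours <- findPuncta(rm2, 1)
    orc <- oracleComponents(rm2)[, , 1]
    expect_equal(punctaCount(ours), max(orc))
    # identical partitions: label images agree up to renaming
    expect_equal(length(unique(paste(punctaLabels(ours), orc))) - 1L,
                 max(orc))
  }
  # 3D: 26-connectivity
  a <- array(0, c(4, 4, 3)); a[1, 1, 1] <- 1; a[2, 2, 2] <- 1
  expect_equal(punctaCount(findPuncta(a, 1)), 1L)
})

test_that("colocalization counts pre puncta sharing pixels with post", {
  lab <- function(m) findPuncta(m, 1)
  pre <- matrix(0, 8, 8); pre[2:3, 2:3] <- 1
  post <- matrix(0, 8, 8); post[3, 3] <- 1
  expect_equal(colocalizePuncta(lab(pre), lab(post))$n_coloc, 1L)
  post2 <- matrix(0, 8, 8); post2[6:7, 6:7] <- 1
  expect_equal(colocalizePuncta(lab(pre), lab(post2))$n_coloc, 0L)
  # one pre punctum overlapping two post puncta counts once
  pre3 <- matrix(0, 8, 8); pre3[4, 1:8] <- 1
  post3 <- matrix(0, 8, 8); post3[4, 2] <- 1; post3[4, 7] <- 1
  cl <- colocalizePuncta(lab(pre3), lab(post3))
  expect_equal(cl$n_coloc, 1L)
  expect_equal(nrow(cl$pairs), 2L)
  expect_error(colocalizePuncta(lab(pre), findPuncta(matrix(0, 4, 4), 1)),
               "shapes")
})

test_that("colocalization equals the all-pairs oracle on random masks", {
  set.seed(4)
  for (rep in 1:6) {
    a <- matrix(rbinom(900, 1, 0.25), 30)
    b <- matrix(rbinom(900, 1, 0.25), 30)
    pa <- findPuncta(a, 1); pb <- findPuncta(b, 1)
    expect_equal(colocalizePuncta(pa, pb)$n_coloc,
                 oracleColoc(punctaLabels(pa), punctaLabels(pb)))
    expect_lte(colocalizePuncta(pa, pb)$n_coloc, punctaCount(pa))
  }
})

test_that("colocalized count is monotone in the channel threshold", {
  # on spot-like (unimodal) puncta, raising a threshold can only shrink
  # each punctum, so the colocalized count cannot increase
  mask <- matrix(1, 120, 120)
  g <- generateSynapseStack(mask, preDensity = 0.3, postDensity = 0.3,
                            colocFraction = 0.5, noiseSd = 0.02, seed = 5)
  pre2d <- splitAndProject(g$pre)[[2]]
  post2d <- splitAndProject(g$post)[[2]]
  postSet <- findPuncta(thresholdChannel(post2d, "fixed", 0.4), 4)
  thr <- c(0.3, 0.45, 0.6, 0.75, 0.9)
  ns <- vapply(thr, function(tv) {
    pre <- findPuncta(thresholdChannel(pre2d, "fixed", tv), 4)
    colocalizePuncta(pre, postSet)$n_coloc
  }, integer(1))
  expect_true(all(diff(ns) <= 0))
  expect_gt(ns[1], 0)
})

test_that("synapse density normalizes the count to astrocyte area", {
  mask <- matrix(1, 10, 10)
  r <- synapseDensity(6, mask, pixelArea = 1)
  expect_equal(r$density_per_um2, 0.06)
  expect_equal(synapseDensity(0, mask, 1)$density_per_um2, 0)
  # doubling pixel area halves the density
  expect_equal(synapseDensity(6, mask, 2)$density_per_um2,
               r$density_per_um2 / 2)
  expect_error(synapseDensity(1, matrix(0, 3, 3), 1), "empty")
})

test_that("image stacks round-trip through multi-page TIFF", {
  skip_if_not_installed("tiff")
  set.seed(6)
  st <- imageStack(array(runif(8 * 8 * 4), c(8, 8, 4)), vs, "pre")
  f <- tempfile(fileext = ".tif")
  sc <- writeImageStack(st, f)
  back <- readImageStack(f, vs, "pre")
  expect_equal(dim(stackData(back)), c(8, 8, 4))
  expect_equal(stackData(back) * sc, stackData(st), tolerance = 1e-4)
})
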