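simpleTree <- function(coords, parent) {
  filamentTree(data.frame(id = seq_len(nrow(coords)), x = coords[, 1],
                          y = coords[, 2], z = coords[, 3], radius = 0.5,
                          parent = parent))
}

test_that("total branch length sums segment lengths", {
  tr <- simpleTree(rbind(c(0, 0, 0), c(3, 4, 0)), c(NA, 1))
  expect_equal(totalBranchLength(tr), 5)
  # Y-shaped: trunk 10 then two branches of 5
  y <- simpleTree(rbind(c(0, 0, 0), c(0, 10, 0), c(3, 14, 0), c(-3, 14, 0)),
                  c(NA, 1, 2, 2))
  expect_equal(totalBranchLength(y), 20)
})

test_that("total branch length matches the naive loop on random trees", {
  set.seed(101)
  for (rep in 1:5) {
    tr <- randomMonotoneTree(200)
    expect_equal(totalBranchLength(tr), oracleTotalLength(tr),
                 tolerance = 1e-9)
  }
})

test_that("Sholl counts follow the shell-straddling rule", {
  # single straight radial branch of length 12: crosses r = 5 and 10
  tr <- simpleTree(rbind(c(0, 0, 0), c(12, 0, 0)), c(NA, 1))
  expect_equal(shollCounts(shollIntersections(tr, 5)), c(1, 1, 0))
  # two branches reaching radial distance 20: superposition
  tr2 <- simpleTree(rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0)),
                    c(NA, 1, 1))
  expect_equal(shollCounts(shollIntersections(tr2, 5))[1:4], c(2, 2, 2, 2))
  expect_error(shollIntersections(tr, step = 0), "step")
})

test_that("Sholl curve matches the dense-resampling oracle", {
  set.seed(202)
  for (rep in 1:12) {
    tr <- randomMonotoneTree(40, stepMean = 5)
    cu <- shollIntersections(tr, 5)
    expect_equal(shollCounts(cu), oracleSholl(tr, 5), tolerance = 0)
    cu2 <- shollIntersections(tr, 5, dimension = 2)
    expect_equal(shollCounts(cu2), oracleSholl(tr, 5, dimension = 2))
  }
})

test_that("curve peak picks the maximum with ties to the smaller radius", {
  expect_equal(peakOfCurve(shollCurve(5, c(1, 4, 4, 2))),
               c(peak_radius = 10, peak_count = 4))
  expect_equal(peakOfCurve(shollCurve(5, c(0, 0))),
               c(peak_radius = 5, peak_count = 0))
  set.seed(9)
  for (rep in 1:5) {
    ct <- rpois(10, 3)
    expect_equal(unname(peakOfCurve(shollCurve(5, ct))["peak_count"]),
                 max(ct))
  }
})

test_that("territory volume is the hull volume and rejects degenerate input", {
  tetra <- simpleTree(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                      c(NA, 1, 1, 1))
  expect_equal(convexHullTerritory(tetra), 1 / 6, tolerance = 1e-12)
  # unit cube plus interior points: interior does not change the volume
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  inner <- matrix(runif(30, 0.2, 0.8), ncol = 3)
  expect_equal(convexHullVolume3d(rbind(cube, inner)), 1, tolerance = 1e-12)
  expect_error(convexHullVolume3d(cube[1:3, ]), "4 distinct points")
  flat <- cbind(runif(10), runif(10), 0)
  expect_error(convexHullVolume3d(flat), "coplanar")
})

test_that("hull volume agrees with the Monte-Carlo hit test", {
  set.seed(303)
  for (rep in 1:3) {
    pts <- matrix(rnorm(3 * 500), ncol = 3)
    h <- convexHull3d(pts)
    # every input point satisfies all facet half-spaces
    viol <- h$normals %*% t(h$points) - h$offsets
    expect_lt(max(viol), 1e-7)
    bb <- apply(pts, 2, range)
    m <- 2e5
    smp <- cbind(runif(m, bb[1, 1], bb[2, 1]), runif(m, bb[1, 2], bb[2, 2]),
                 runif(m, bb[1, 3], bb[2, 3]))
    inside <- rep(TRUE, m)
    for (f in seq_along(h$offsets))
      inside <- inside & (smp %*% h$normals[f, ] <= h$offsets[f] + 1e-12)
    vbox <- prod(bb[2, ] - bb[1, ])
    expect_equal(mean(inside) * vbox, h$volume, tolerance = 0.01)
  }
})

test_that("morphometrics obey scaling, rigid-motion and monotonicity laws", {
  set.seed(404)
  tr <- randomMonotoneTree(80)
  nd <- treeNodes(tr)
  s <- 2.7
  scaled <- filamentTree(transform(nd, x = x * s, y = y * s, z = z * s))
  expect_equal(totalBranchLength(scaled), s * totalBranchLength(tr),
               tolerance = 1e-12)
  expect_equal(convexHullTerritory(scaled), s^3 * convexHullTerritory(tr),
               tolerance = 1e-9)
  # rotation about the root leaves Sholl counts unchanged
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- as.matrix(nd[, c("x", "y", "z")]) %*% t(R)
  rtr <- filamentTree(transform(nd, x = rot[, 1], y = rot[, 2], z = rot[, 3]))
  expect_equal(shollCounts(shollIntersections(rtr, 5)),
               shollCounts(shollIntersections(tr, 5)))
  # translation of the whole tree with its root
  ttr <- filamentTree(transform(nd, x = x + 11, y = y - 4, z = z + 2))
  expect_equal(shollCounts(shollIntersections(ttr, 5)),
               shollCounts(shollIntersections(tr, 5)))
  # adding a node never decreases length or territory
  far <- max(abs(as.matrix(nd[, c("x", "y", "z")]))) + 5
  nd2 <- rbind(nd, data.frame(id = max(nd$id) + 1L, type = 3L, x = far,
                              y = far, z = far, radius = 0.5,
                              parent = nd$id[1]))
  tr2 <- filamentTree(nd2)
  expect_gte(totalBranchLength(tr2), totalBranchLength(tr))
  expect_gte(convexHullTerritory(tr2), convexHullTerritory(tr))
  # curve is zero beyond the farthest node
  d <- sqrt(nd$x^2 + nd$y^2 + nd$z^2)
  cu <- shollIntersections(tr, 5)
  expect_true(all(shollCounts(cu)[shollRadii(cu) >= max(d)] == 0))
})
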