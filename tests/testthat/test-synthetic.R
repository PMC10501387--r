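test_that("tree generation is a pure function of params and seed", {
  p <- conditionPreset("monoculture")
  a <- generateAstrocyteTree(p, seed = 42)
  b <- generateAstrocyteTree(p, seed = 42)
  expect_identical(treeNodes(a$tree), treeNodes(b$tree))
  expect_identical(a$truth, b$truth)
  c <- generateAstrocyteTree(p, seed = 43)
  expect_false(identical(treeNodes(a$tree), treeNodes(c$tree)))
})

test_that("truth records match the measured total length exactly", {
  set.seed(30)
  for (nm in c("monoculture", "knockdown", "control_invivo")) {
    g <- generateAstrocyteTree(conditionPreset(nm))
    expect_equal(totalBranchLength(g$tree), g$truth$total_length,
                 tolerance = 1e-9)
    expect_equal(nrow(treeNodes(g$tree)), g$truth$n_nodes)
  }
})

test_that("degenerate growth parameters error after bounded retries", {
  p <- conditionPreset("monoculture", nPrimaryBase = 0L, nPrimarySpread = 0L)
  expect_error(generateAstrocyteTree(p, seed = 1), "degenerate")
})

test_that("preset knockdown arbors are stunted relative to control", {
  set.seed(31)
  ctrl <- generateAstrocytePopulation("control_coculture", 15, 31)
  kd <- generateAstrocytePopulation("knockdown", 15, 31)
  lc <- mean(sapply(ctrl$trees, totalBranchLength))
  lk <- mean(sapply(kd$trees, totalBranchLength))
  expect_gt(lc / lk, 2)
  pc <- mean(sapply(ctrl$trees, function(tr)
    peakOfCurve(shollIntersections(tr, 5))["peak_count"]))
  pk <- mean(sapply(kd$trees, function(tr)
    peakOfCurve(shollIntersections(tr, 5))["peak_count"]))
  expect_gt(pc, pk)
})

test_that("tree rasterisation marks the expected voxels deterministically", {
  # single axis-aligned thin segment: foreground count ~ length / voxel
  tr <- filamentTree(data.frame(id = 1:2, x = c(2, 14), y = 8, z = 2,
                                radius = c(0.01, 0.01), parent = c(NA, 1)))
  m <- renderTreeMask(tr, c(z = 1, y = 1, x = 1), dims = c(16L, 16L, 4L),
                      origin = c(0, 0, 0))
  count <- sum(stackData(m))
  expect_gte(count, 12 - 2)
  expect_lte(count, 12 + 2 + 1)  # soma sphere adds its root voxel
  m2 <- renderTreeMask(tr, c(z = 1, y = 1, x = 1), dims = c(16L, 16L, 4L),
                       origin = c(0, 0, 0))
  expect_identical(stackData(m), stackData(m2))
  expect_error(renderTreeMask(tr, c(z = 1, y = 1, x = 1),
                              dims = c(4L, 4L, 2L), origin = c(0, 0, 0)),
               "overflow")
  expect_error(renderTreeMask(tr, c(z = -1, y = 1, x = 1), c(8L, 8L, 2L)),
               "> 0")
})

test_that("synapse stacks honour the programmed colocalization fraction", {
  mask <- matrix(1, 80, 80)
  g0 <- generateSynapseStack(mask, colocFraction = 0, seed = 7)
  expect_equal(g0$truth$n_coloc_planted, 0L)
  g1 <- generateSynapseStack(mask, colocFraction = 1, seed = 7)
  expect_equal(g1$truth$n_coloc_planted, g1$truth$n_pre)
  # seeded determinism
  a <- generateSynapseStack(mask, seed = 8)
  b <- generateSynapseStack(mask, seed = 8)
  expect_identical(stackData(a$pre), stackData(b$pre))
  expect_identical(stackData(a$post), stackData(b$post))
  expect_error(generateSynapseStack(mask, punctumRadius = 0.01, seed = 1),
               "smaller than one voxel")
})

test_that("chance overlap at f = 0 matches the Poisson approximation", {
  mask <- matrix(1, 150, 150)   # 15 x 15 um at 0.1 um pixels
  nPre <- 0; nChance <- 0
  for (s in 1:10) {
    g <- generateSynapseStack(mask, colocFraction = 0, seed = 100 + s)
    q <- quantifySynapses(g$pre, g$post, g$astro,
                          threshold = list(method = "fixed", value = 0.4))
    nPre <- nPre + g$truth$n_pre
    nChance <- nChance + sum(q$n_coloc)
  }
  # analytic chance-overlap rate: a pre punctum is hit when a post centre
  # falls within the dilated overlap disc of suprathreshold radius
  rEff <- 0.15 * sqrt(2 * log(1 / 0.4))
  pChance <- 1 - exp(-0.12 * pi * (2 * rEff)^2)
  expect_equal(nChance / nPre, pChance, tolerance = 0.75)
  expect_lt(nChance / nPre, 0.2)
})

test_that("the FISH design and dataset have the stated layout", {
  expect_equal(designSize(studyDesign()), 180L)
  man <- designManifest(studyDesign())
  expect_equal(nrow(man), 180L)
  expect_equal(length(unique(man$animal)), 12L)       # 3 per timepoint
  expect_equal(sum(man$timepoint == "P14"), 45L)      # 5 layers x 9
  ds <- generateFishDataset(studyDesign(layers = "L1", timepoints = "P7"),
                            expression = 0.05, seed = 2)
  expect_length(ds$images, 9L)
  ds2 <- generateFishDataset(studyDesign(layers = "L1", timepoints = "P7"),
                             expression = 0.05, seed = 2)
  expect_identical(ds$truth, ds2$truth)
  expect_identical(stackData(ds$images[[3]]$mrna),
                   stackData(ds2$images[[3]]$mrna))
  bad <- defaultFishExpression()[-1, ]
  expect_error(generateFishDataset(studyDesign(), expression = bad, seed = 1),
               "missing stratum")
})

test_that("truth tables carry mean-preserving programmed expression", {
  des <- studyDesign(layers = c("L1", "L4"), timepoints = c("P1", "P7"))
  big <- do.call(rbind, lapply(1:60, function(s)
    generateFishDataset(des, expression = 0.05, render = FALSE,
                        seed = 1000 + s)$truth))
  expect_equal(mean(big$expression_true), 0.05, tolerance = 0.02)
})
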