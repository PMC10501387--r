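test_that("nested t-test recovers an exact constant difference", {
  v <- c(rep(1, 8), rep(1 + 2.5, 8))
  a <- rep(1:4, each = 4)
  g <- rep(c("A", "B"), each = 8)
  r <- nestedTTest(v, a, g)
  expect_equal(r$estimate, 2.5, tolerance = 1e-8)
  expect_error(nestedTTest(v[1:12], a[1:12], g[1:12]), "2 animals")
})

test_that("nested t-test rejects less often than the naive cell-level t-test", {
  set.seed(21)
  nestedP <- naiveP <- numeric(150)
  for (i in seq_len(150)) {
    a <- rep(1:10, each = 4)
    g <- rep(c("A", "B"), each = 20)
    v <- rnorm(10, 0, 1)[a] + rnorm(40, 0, 1)   # null with animal variance
    nestedP[i] <- nestedTTest(v, a, g)$p
    naiveP[i] <- t.test(v ~ g)$p.value
  }
  expect_lt(mean(nestedP < 0.05), mean(naiveP < 0.05))
  expect_gt(mean(naiveP < 0.05), 0.09)  # pseudoreplication inflates error
  expect_true(all(nestedP >= 0 & nestedP <= 1))
})

test_that("nested ANOVA handles identical groups and collapses to the t-test", {
  set.seed(22)
  base <- rnorm(6)
  v <- rep(base, each = 3) + rnorm(18, 0, 0.3)
  a <- rep(1:6, each = 3)
  # 3 identical groups, 2 animals each
  g3 <- rep(c("A", "B", "C"), each = 6)
  r3 <- nestedAnova(v, a, g3)
  expect_gt(r3$omnibus_p, 0.05)
  expect_true(all(r3$contrasts$p_adj >= 0 & r3$contrasts$p_adj <= 1))
  # two groups: estimate agrees with the nested t-test
  g2 <- rep(c("A", "B"), each = 9)
  a2 <- rep(1:6, each = 3)
  r2 <- nestedAnova(v, a2, g2)
  t2 <- nestedTTest(v, a2, g2)
  expect_equal(abs(r2$contrasts$estimate), abs(t2$estimate), tolerance = 1e-6)
})

test_that("a strongly shifted group is flagged by the nested ANOVA", {
  set.seed(23)
  a <- rep(1:8, each = 4)
  g <- rep(c("A", "B", "C", "D"), each = 8)
  animalEff <- rnorm(8, 0, 1)
  v <- animalEff[a] + rnorm(32, 0, 0.5)
  v[g == "D"] <- v[g == "D"] + 5   # 5 between-animal SDs
  r <- nestedAnova(v, a, g)
  expect_lt(r$omnibus_p, 0.05)
  dCon <- grepl("D", r$contrasts$contrast)
  expect_true(all(r$contrasts$p_adj[dCon] < 0.05))
})

test_that("two-way ANOVA with reference contrasts flags a planted decrease", {
  set.seed(24)
  d <- expand.grid(layer = c("L1", "L2/3", "L4", "L5", "L6"),
                   timepoint = c("P1", "P7", "P14", "P21"),
                   animal = 1:3, stringsAsFactors = FALSE)
  d$value <- 0.05 + rnorm(nrow(d), 0, 0.004)
  drop <- d$layer == "L1" & d$timepoint == "P21"
  d$value[drop] <- d$value[drop] - 0.03
  r <- twoWayAnovaDunnett(d, reference = "P1")
  hit <- r$contrasts$layer == "L1" & grepl("P21", r$contrasts$contrast)
  expect_true(any(hit))
  expect_lt(r$contrasts$p_adj[hit], 0.05)
  expect_gt(min(r$contrasts$p_adj[!hit]), 0.05)
  # permuting row order changes nothing
  r2 <- twoWayAnovaDunnett(d[sample(nrow(d)), ], reference = "P1")
  o1 <- r$contrasts[order(r$contrasts$layer, r$contrasts$contrast), ]
  o2 <- r2$contrasts[order(r2$contrasts$layer, r2$contrasts$contrast), ]
  expect_equal(o1$estimate, o2$estimate, tolerance = 1e-10)
  # the joint mvt adjustment integrates quasi-randomly; agreement is to
  # numerical integration accuracy, estimates are exact
  expect_equal(o1$p_adj, o2$p_adj, tolerance = 1e-3)
  expect_error(twoWayAnovaDunnett(d, reference = "P99"), "absent")
})

test_that("the normality gate picks the branch the samples call for", {
  set.seed(26)
  x <- rnorm(50); y <- rnorm(50, 0.2)
  r <- normalityGate(x, y)
  expect_equal(r$branch, "parametric")
  yl <- exp(rnorm(50, 0, 1.5))
  r2 <- normalityGate(x, yl)
  expect_equal(r2$branch, "nonparametric")
  # identical samples: p ~ 1 on whichever branch runs
  z <- rnorm(30)
  r3 <- normalityGate(z, z)
  expect_gt(r3$p, 0.9)
  expect_error(normalityGate(rnorm(2), rnorm(10)), "n >= 3")
})

test_that("experiment QC applies the strict peak thresholds", {
  expect_equal(qcExperiment(c(19, 19), "coculture")$decision, "exclude")
  expect_equal(qcExperiment(c(20, 20), "coculture")$decision, "keep")
  expect_equal(qcExperiment(5, "monoculture")$decision, "exclude")
  expect_equal(qcExperiment(6, "monoculture")$decision, "keep")
  expect_equal(qcExperiment(1, "in_vivo")$decision, "keep")
  expect_error(qcExperiment(numeric(0), "coculture"), "no control")
  # idempotent and a pure function of the control peaks
  expect_identical(qcExperiment(c(25, 18), "coculture"),
                   qcExperiment(c(25, 18), "coculture"))
})

test_that("densitometry fold change is a ratio of ratios", {
  expect_equal(densitometryFold(2, 10, 0.1), 2)
  expect_equal(densitometryFold(3, 12, 0.25), 1)
  expect_equal(densitometryFold(4, 20, 0.1), densitometryFold(8, 40, 0.1))
  expect_error(densitometryFold(1, 0, 0.1), "> 0")
})

test_that("duplicated conditions give an exactly null curve contrast", {
  set.seed(26)
  trees <- replicate(8, generateAstrocyteTree(conditionPreset("monoculture"))$tree,
                     simplify = FALSE)
  curves <- lapply(c(trees, trees), shollIntersections, step = 5)
  cd <- curvesToDataset(curves, cell_id = paste0("c", 1:16),
                        condition = rep(c("A", "B"), each = 8),
                        experiment = rep(rep(c("E1", "E2"), each = 4), 2))
  r <- shollLmmCompare(cd, "monoculture")
  expect_lt(abs(r$contrasts$estimate), 1e-8)
  expect_error(shollLmmCompare(cd[cd$condition == "A", ], "monoculture"),
               "2 conditions")
})

test_that("curve model rejects cells off the common radius grid", {
  set.seed(27)
  trees <- replicate(4, generateAstrocyteTree(conditionPreset("monoculture"))$tree,
                     simplify = FALSE)
  curves <- lapply(trees, shollIntersections, step = 5)
  cd <- curvesToDataset(curves, paste0("c", 1:4), rep(c("A", "B"), each = 2))
  bad <- cd[!(cd$cell_id == "c1" & cd$radius == max(cd$radius)), ]
  expect_error(shollLmmCompare(bad, "monoculture"), "common radius grid")
})
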