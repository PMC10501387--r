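# Hierarchical inference for nested designs (cells within animals or
# experiments): mixed-model Sholl-curve comparison with Tukey-adjusted
# contrasts, nested t-test and one-way ANOVA, two-way ANOVA with Dunnett
# reference contrasts, a normality-gated two-sample test, experiment QC
# and the densitometry fold change.

# tidy an emmeans contrast summary; the test statistic column is t.ratio
# under finite df and z.ratio under the asymptotic fallback
contrastFrame <- function(cs) {
  cs <- as.data.frame(cs)
  stat <- if (!is.null(cs$t.ratio)) cs$t.ratio else cs$z.ratio
  data.frame(contrast = cs$contrast, estimate = cs$estimate, SE = cs$SE,
             df = if (!is.null(cs$df)) cs$df else NA_real_,
             t = stat, p_adj = cs$p.value)
}

#' Assemble Sholl curves into a long-format curve dataset
#'
#' Pads all curves with zeros to a common radius grid (the longest curve),
#' as required by the curve-comparison model.
#'
#' @param curves list of [ShollCurve-class].
#' @param cell_id,condition,animal,experiment vectors parallel to `curves`.
#' @param maxRadius optional fixed analysis radius (micrometres): the
#'   common grid ends at the last shell `<= maxRadius` instead of at the
#'   single farthest-reaching cell. Shells beyond a cell's own curve are
#'   structural zeros either way; a cap keeps one sprawling outlier from
#'   padding the whole dataset with empty shells.
#' @return long data.frame (`cell_id`, `experiment`, `animal`, `condition`,
#'   `radius`, `count`).
#' @export
curvesToDataset <- function(curves, cell_id, condition, animal = NULL,
                            experiment = NULL, maxRadius = NULL) {
  n <- length(curves)
  if (is.null(animal)) animal <- rep(NA_character_, n)
  if (is.null(experiment)) experiment <- rep("E1", n)
  step <- curves[[1L]]@step
  maxlen <- max(vapply(curves, function(cu) length(shollCounts(cu)), 1L))
  if (!is.null(maxRadius)) maxlen <- min(maxlen, max(1L, floor(maxRadius / step)))
  radii <- step * seq_len(maxlen)
  do.call(rbind, lapply(seq_len(n), function(i) {
    if (abs(curves[[i]]@step - step) > 1e-9)
      stop("curves do not share a common radius step")
    ct <- shollCounts(curves[[i]])
    length(ct) <- maxlen                      # truncate or NA-extend
    ct[is.na(ct)] <- 0L
    data.frame(cell_id = cell_id[i], experiment = experiment[i],
               animal = animal[i], condition = condition[i],
               radius = radii, count = ct)
  }))
}

#' Mixed-model comparison of Sholl curves between conditions
#'
#' Fits `count ~ condition * radius` with radius as a categorical factor
#' and a random intercept per cell nested in the grouping unit
#' (`experiment` for culture data, `animal` for in vivo data). Condition
#' contrasts are differences of marginal means averaged over the radius
#' grid, with Tukey family-wise adjustment and Satterthwaite degrees of
#' freedom.
#'
#' @param data long data.frame as from [curvesToDataset()]: columns
#'   `cell_id`, `experiment`, `animal`, `condition`, `radius`, `count`.
#' @param cultureType `"coculture"`, `"monoculture"` or `"in_vivo"`
#'   (selects the nesting unit).
#' @return list with `contrasts` (data.frame: contrast, estimate, SE, df,
#'   t, p_adj), `emmeans` (condition marginal means), `model` (the lmer
#'   fit) and `formula`.
#' @export
shollLmmCompare <- function(data, cultureType = c("coculture", "monoculture",
                                                  "in_vivo")) {
  cultureType <- match.arg(cultureType)
  req <- c("cell_id", "condition", "radius", "count")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0L)
    stop("data is missing column(s): ", paste(miss, collapse = ", "))
  unit <- if (cultureType == "in_vivo") "animal" else "experiment"
  if (is.null(data[[unit]])) stop("data is missing column: ", unit)
  conds <- unique(data$condition)
  if (length(conds) < 2L) stop("need at least 2 conditions")
  cellsPer <- tapply(data$cell_id, data$condition,
                     function(v) length(unique(v)))
  if (any(cellsPer < 2L))
    stop("singular design: fewer than 2 cells in condition ",
         names(cellsPer)[which(cellsPer < 2L)[1L]])
  # common radius grid check
  grids <- tapply(data$radius, data$cell_id, function(r)
    paste(sort(unique(r)), collapse = ","))
  if (length(unique(grids)) != 1L)
    stop("cells are not on a common radius grid")
  d <- data.frame(count = data$count,
                  condition = factor(data$condition),
                  radius = factor(data$radius),
                  cell = factor(paste(data[[unit]], data$cell_id, sep = ":")),
                  unit = factor(data[[unit]]))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(count ~ condition * radius + (1 | unit) + (1 | cell),
                   data = d,
                   control = lme4::lmerControl(calc.derivs = FALSE))))
  emm <- suppressMessages(
    emmeans::emmeans(fit, "condition", lmer.df = "satterthwaite"))
  cons <- emmeans::contrast(emm, method = "pairwise", adjust = "tukey")
  contrasts <- contrastFrame(summary(cons))
  list(contrasts = contrasts, emmeans = as.data.frame(summary(emm)),
       model = fit,
       formula = paste("count ~ condition * radius + (1 |", unit,
                       ") + (1 | cell), radius categorical"))
}

#' Nested two-sample t-test (cells within animals)
#'
#' Mixed model `value ~ group + (1 | animal)` with a two-sided
#' Satterthwaite test on the group coefficient — the mixed-model
#' equivalent of a nested t-test, avoiding pseudoreplication from
#' treating cells as independent.
#'
#' @param values numeric response per cell.
#' @param animals animal id per cell (each animal in exactly one group).
#' @param groups group label per cell (exactly 2 levels).
#' @return list: `estimate` (group difference, level2 - level1), `se`,
#'   `df`, `statistic`, `p`, `groups`.
#' @export
nestedTTest <- function(values, animals, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("nested t-test needs exactly 2 groups")
  tab <- table(unique(data.frame(a = animals, g = groups))$g)
  if (any(tab < 2L))
    stop("need at least 2 animals per group; got ",
         paste(tab, collapse = " and "))
  d <- data.frame(value = values, animal = factor(animals), group = groups)
  # degenerate variance structures (zero noise) legitimately trip the
  # optimizer's convergence checks; they are handled by the fallback below
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(value ~ group + (1 | animal), data = d))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    co <- coef(summary(fit))
    est <- co[2L, "Estimate"]
    out <- list(estimate = unname(est), se = unname(co[2L, "Std. Error"]),
                df = unname(co[2L, "df"]), statistic = unname(co[2L, "t value"]),
                p = unname(co[2L, "Pr(>|t|)"]), groups = levels(groups),
                method = "mixed model, Satterthwaite df")
  } else {
    # degenerate variance structure (e.g. exactly constant values):
    # fall back to a Welch t-test on animal means
    am <- aggregate(value ~ animal + group, data = d, FUN = mean)
    if (sd(am$value[am$group == levels(groups)[1L]]) == 0 &&
        sd(am$value[am$group == levels(groups)[2L]]) == 0) {
      est <- diff(tapply(am$value, am$group, mean))
      out <- list(estimate = unname(est), se = 0, df = NA_real_,
                  statistic = if (est == 0) 0 else Inf,
                  p = if (est == 0) 1 else 0, groups = levels(groups),
                  method = "degenerate (zero variance)")
    } else {
      tt <- t.test(value ~ group, data = am)
      out <- list(estimate = unname(tt$estimate[2L] - tt$estimate[1L]),
                  se = unname(tt$stderr), df = unname(tt$parameter),
                  statistic = unname(tt$statistic), p = tt$p.value,
                  groups = levels(groups),
                  method = "Welch t on animal means (fallback)")
    }
  }
  # estimate is level2 - level1 from the model coefficient; NaN p can
  # arise from zero residual variance
  if (is.na(out$p)) out$p <- if (abs(out$estimate) < 1e-12) 1 else 0
  out
}

#' Nested one-way ANOVA with Tukey contrasts
#'
#' Mixed model `value ~ group + (1 | animal)`; omnibus F test with
#' Satterthwaite degrees of freedom and pairwise Tukey-adjusted contrasts
#' of the group marginal means.
#'
#' @inheritParams nestedTTest
#' @return list: `omnibus_p`, `anova` (the F table), `contrasts`
#'   (data.frame as in [shollLmmCompare()]), `model`.
#' @export
nestedAnova <- function(values, animals, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  tab <- table(unique(data.frame(a = animals, g = groups))$g)
  if (any(tab < 2L)) stop("need at least 2 animals per group")
  d <- data.frame(value = values, animal = factor(animals), group = groups)
  fit <- lmerTest::lmer(value ~ group + (1 | animal), data = d)
  an <- anova(fit)  # Satterthwaite type III
  emm <- emmeans::emmeans(fit, "group", lmer.df = "satterthwaite")
  cons <- summary(emmeans::contrast(emm, "pairwise", adjust = "tukey"))
  list(omnibus_p = an[["Pr(>F)"]][1L], anova = an,
       contrasts = contrastFrame(cons), model = fit)
}

#' Two-way ANOVA with Dunnett contrasts against a reference timepoint
#'
#' Fits `value ~ layer * timepoint` on animal-level means, reports the
#' two-way ANOVA table, and tests every timepoint against the reference
#' within each layer. All layer-by-timepoint contrasts of the analysis are
#' adjusted as a single family (generalized Dunnett via the multivariate-t
#' distribution of the contrast vector).
#'
#' @param table data.frame with columns `value`, `layer`, `timepoint` (one
#'   row per animal-level mean).
#' @param reference reference timepoint level (default `"P1"`).
#' @return list: `anova` (two-way table), `contrasts` (data.frame with
#'   `layer`, `contrast`, `estimate`, `SE`, `df`, `t`, `p_adj`).
#' @export
twoWayAnovaDunnett <- function(table, reference = "P1") {
  req <- c("value", "layer", "timepoint")
  miss <- setdiff(req, names(table))
  if (length(miss) > 0L)
    stop("table is missing column(s): ", paste(miss, collapse = ", "))
  if (!reference %in% table$timepoint)
    stop("reference level '", reference, "' absent from timepoint")
  d <- data.frame(value = table$value, layer = factor(table$layer),
                  timepoint = stats::relevel(factor(table$timepoint),
                                             ref = reference))
  fit <- lm(value ~ layer * timepoint, data = d)
  an <- anova(fit)
  emm <- emmeans::emmeans(fit, ~ timepoint | layer)
  cons <- emmeans::contrast(emm, "trt.vs.ctrl", ref = reference)
  # one multiplicity family for the whole panel: re-adjust jointly.
  # the mvt quantile is quasi-random; seed locally for reproducibility
  seedKeep <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(20231L)
  cs <- as.data.frame(summary(rbind(cons), adjust = "mvt"))
  if (!is.null(seedKeep)) assign(".Random.seed", seedKeep, globalenv())
  out <- contrastFrame(cs)
  out <- cbind(layer = cs$layer, out)
  list(anova = an, contrasts = out)
}

#' Normality-gated two-sample comparison
#'
#' Shapiro-Wilk on each sample; if either rejects normality at 0.05, a
#' two-sided Mann-Whitney U test is run, otherwise a Welch t-test.
#'
#' @param x,y numeric samples, each of length >= 3.
#' @return list: `branch` (`"parametric"` or `"nonparametric"`),
#'   `shapiro_p` (both p-values), `p`, `statistic`, `test` (htest).
#' @export
normalityGate <- function(x, y) {
  if (length(x) < 3L || length(y) < 3L)
    stop("each sample needs n >= 3")
  sw <- c(shapiro.test(x)$p.value, shapiro.test(y)$p.value)
  if (any(sw < 0.05)) {
    ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    branch <- "nonparametric"
  } else {
    ht <- t.test(x, y)
    branch <- "parametric"
  }
  list(branch = branch, shapiro_p = sw, p = ht$p.value,
       statistic = unname(ht$statistic), test = ht)
}

#' Experiment-level quality control on control Sholl curves
#'
#' Healthy control astrocytes must show a mean peak intersection count of
#' at least 20 in astrocyte-neuron co-cultures and at least 6 in
#' astrocyte-only cultures; an experiment whose control mean falls below
#' the threshold (strict `<`) is excluded wholesale. No QC rule applies in
#' vivo.
#'
#' @param peaks numeric vector of control-cell peak intersection counts
#'   for one experiment.
#' @param cultureType `"coculture"`, `"monoculture"` or `"in_vivo"`.
#' @return list: `decision` (`"keep"`/`"exclude"`), `mean_peak`,
#'   `threshold`.
#' @export
qcExperiment <- function(peaks, cultureType = c("coculture", "monoculture",
                                                "in_vivo")) {
  cultureType <- match.arg(cultureType)
  if (length(peaks) == 0L) stop("no control cells supplied")
  mp <- mean(peaks)
  thr <- switch(cultureType, coculture = 20, monoculture = 6, in_vivo = -Inf)
  list(decision = if (mp < thr) "exclude" else "keep",
       mean_peak = mp, threshold = thr)
}

#' Densitometric fold change of surface over total signal
#'
#' `F = (surface / total) / reference_ratio`.
#'
#' @param surface,total densitometric intensities (> 0).
#' @param referenceRatio surface/total ratio of the reference condition
#'   (> 0).
#' @return fold change.
#' @export
densitometryFold <- function(surface, total, referenceRatio) {
  if (any(total <= 0) || any(referenceRatio <= 0) || any(surface <= 0))
    stop("intensities and reference ratio must be > 0")
  (surface / total) / referenceRatio
}
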