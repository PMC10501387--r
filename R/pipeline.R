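# End-to-end runs: simulate/load -> quantify -> infer, with a config
# snapshot, JSON analysis report and deterministic CSV outputs in the
# output directory. These functions are the package's orchestration
# surface; each stage is an exported operation that can also be called
# directly.

writeRunArtifacts <- function(out, config, report, tables) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  cfg$trees <- NULL; cfg$images <- NULL; cfg$stacks <- NULL
  yaml::write_yaml(cfg, file.path(out, "config.yaml"))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  for (nm in names(tables))
    write.csv(tables[[nm]], file.path(out, paste0(nm, ".csv")),
              row.names = FALSE)
  invisible(out)
}

#' Run the morphometry pipeline on a set of reconstructions
#'
#' Computes per-cell metrics (total branch length, Sholl curve and peak,
#' territory volume), applies experiment-level QC on control cells,
#' compares Sholl curves between conditions with the mixed model and
#' territory/total-length with the nested t-test (two conditions) or
#' nested ANOVA.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{manifest}{data.frame with `cell_id`, `condition`, `animal`,
#'       `experiment` and either `path` (SWC file) or nothing if `trees`
#'       is given.}
#'     \item{trees}{optional named list of [FilamentTree-class] keyed by
#'       `cell_id` (bypasses SWC reading).}
#'     \item{step}{Sholl step, default 5.}
#'     \item{dimension}{2 or 3, default 3.}
#'     \item{cultureType}{`"coculture"`, `"monoculture"` or `"in_vivo"`.}
#'     \item{controlCondition}{label of the control condition for QC.}
#'     \item{territory}{compute hull volumes (default TRUE).}
#'     \item{out}{output directory.}
#'   }
#' @return invisibly, list with `metrics`, `sholl` (contrast table),
#'   `territory` (nested test), `excluded` (experiments dropped by QC).
#' @export
runMorphometry <- function(config) {
  man <- config$manifest
  if (is.null(man) || nrow(man) == 0L) stop("empty manifest")
  req <- c("cell_id", "condition", "animal", "experiment")
  miss <- setdiff(req, names(man))
  if (length(miss) > 0L)
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  step <- config$step %||% 5
  dimension <- config$dimension %||% 3L
  cultureType <- config$cultureType %||% "coculture"
  control <- config$controlCondition %||% man$condition[1L]
  territory <- config$territory %||% TRUE
  trees <- if (!is.null(config$trees)) config$trees[man$cell_id]
           else lapply(man$path, readSWC)
  metrics <- do.call(rbind, lapply(seq_len(nrow(man)), function(i)
    cellMetrics(trees[[i]], step = step, dimension = dimension,
                territory = territory,
                cell_id = man$cell_id[i], condition = man$condition[i],
                animal = man$animal[i], experiment = man$experiment[i])))
  # experiment-level QC on control cells
  excluded <- character(0)
  qc <- list()
  for (ex in unique(metrics$experiment)) {
    pk <- metrics$peak_count[metrics$experiment == ex &
                             metrics$condition == control]
    if (length(pk) == 0L) stop("experiment ", ex, " has no control cells")
    q <- qcExperiment(pk, cultureType)
    qc[[ex]] <- q
    if (q$decision == "exclude") excluded <- c(excluded, ex)
  }
  kept <- metrics[!metrics$experiment %in% excluded, , drop = FALSE]
  if (length(excluded) > 0L)
    message("QC excluded experiment(s): ", paste(excluded, collapse = ", "))
  sholl <- NULL; terr <- NULL
  keptTrees <- trees[!man$experiment %in% excluded]
  keptMan <- man[!man$experiment %in% excluded, , drop = FALSE]
  if (length(unique(kept$condition)) >= 2L) {
    curves <- lapply(keptTrees, shollIntersections, step = step,
                     dimension = dimension)
    cd <- curvesToDataset(curves, keptMan$cell_id, keptMan$condition,
                          keptMan$animal, keptMan$experiment)
    sholl <- shollLmmCompare(cd, cultureType)
    nest <- if (cultureType == "in_vivo") kept$animal else kept$experiment
    resp <- if (territory) kept$territory_um3 else kept$total_length_um
    terr <- if (length(unique(kept$condition)) == 2L)
      nestedTTest(resp, nest, kept$condition)
    else
      nestedAnova(resp, nest, kept$condition)
  }
  report <- list(
    analysis = "morphometry", sholl_step_um = step, dimension = dimension,
    culture_type = cultureType, control_condition = control,
    qc = lapply(qc, function(q) q[c("decision", "mean_peak", "threshold")]),
    excluded_experiments = excluded,
    sholl_model = sholl$formula,
    sholl_contrasts = sholl$contrasts,
    territory_test = terr[setdiff(names(terr), c("model"))])
  out <- config$out %||% tempfile("morphometry-")
  writeRunArtifacts(out, config, report,
                    list(metrics = metrics,
                         sholl_contrasts = sholl$contrasts %||% data.frame()))
  invisible(list(metrics = metrics, sholl = sholl, territory = terr,
                 excluded = excluded, out = out))
}

#' Run the synapse-density pipeline on three-channel stacks
#'
#' Quantifies each image with [quantifySynapses()] and compares groups on
#' animal-mean densities with the nested t-test.
#'
#' @param config list with elements `stacks` (list per image: `pre`,
#'   `post`, `astro` [ImageStack-class]), `manifest` (data.frame
#'   `image_id`, `group`, `animal`), plus optional `substackThickness`,
#'   `threshold` (list method/value), `minSize`, `mode`, `out`.
#' @return invisibly, list with `densities` (per image/substack), `test`
#'   (nested t-test on animal means, `NULL` if only one group).
#' @export
runSynapse <- function(config) {
  man <- config$manifest
  stacks <- config$stacks
  if (is.null(man) || is.null(stacks)) stop("config needs manifest and stacks")
  req <- c("image_id", "group", "animal")
  miss <- setdiff(req, names(man))
  if (length(miss) > 0L)
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  thr <- config$threshold %||% list(method = "percentile", value = 99)
  rows <- lapply(seq_len(nrow(man)), function(i) {
    st <- stacks[[man$image_id[i]]]
    if (is.null(st$pre) || is.null(st$post) || is.null(st$astro))
      stop("image ", man$image_id[i], " is missing a channel (need pre/post/astro)")
    r <- quantifySynapses(st$pre, st$post, st$astro,
                          substackThickness = config$substackThickness %||% 1.02,
                          threshold = thr,
                          minSize = config$minSize %||% 4L,
                          mode = config$mode %||% "pre")
    r$image_id <- man$image_id[i]; r$group <- man$group[i]
    r$animal <- man$animal[i]
    r
  })
  dens <- do.call(rbind, rows)
  perImage <- aggregate(density_per_um2 ~ image_id + group + animal,
                        data = dens, FUN = mean)
  test <- NULL
  if (length(unique(man$group)) == 2L)
    test <- nestedTTest(perImage$density_per_um2, perImage$animal,
                        perImage$group)
  report <- list(analysis = "synapse", threshold = thr,
                 substack_thickness_um = config$substackThickness %||% 1.02,
                 group_test = test[setdiff(names(test), "model")])
  out <- config$out %||% tempfile("synapse-")
  writeRunArtifacts(out, config, report,
                    list(densities = dens, image_densities = perImage))
  invisible(list(densities = dens, perImage = perImage, test = test,
                 out = out))
}

#' Run the RNA-FISH expression pipeline
#'
#' Quantifies every image (soma segmentation, mRNA volume, expression
#' score), aggregates to animal means, runs the layer-wise nested one-way
#' ANOVA per timepoint and the two-way ANOVA with Dunnett contrasts of
#' each timepoint against the reference.
#'
#' @param config list with elements `images` (list per image:
#'   `reporter`, `mrna`, `neuron`), `manifest` (data.frame `image_id`,
#'   `timepoint`, `animal`, `section`, `layer`), plus optional
#'   `smoothSigma`, `mrnaThreshold`, `reference`, `out`.
#' @return invisibly, list with `cells` (per-cell table), `summary`
#'   (from [aggregateExpression()]), `layerAnova` (per timepoint),
#'   `timepointDunnett`.
#' @export
runFish <- function(config) {
  man <- config$manifest
  images <- config$images
  if (is.null(man) || is.null(images)) stop("config needs manifest and images")
  if (length(images) != nrow(man))
    stop("manifest/images mismatch: ", nrow(man), " rows vs ",
         length(images), " images")
  thr <- config$mrnaThreshold %||% 0.5
  rows <- lapply(seq_len(nrow(man)), function(i) {
    im <- images[[i]]
    q <- quantifyFishImage(im$reporter, im$mrna,
                           smoothSigma = config$smoothSigma %||% 0.3,
                           mrnaThreshold = thr)
    cbind(man[i, , drop = FALSE], q)
  })
  cells <- do.call(rbind, rows)
  summ <- aggregateExpression(cells)
  # layer effect within each timepoint (nested: animals within groups are
  # crossed with layer here, so the one-way ANOVA runs on animal means)
  layerAnova <- lapply(split(summ$animal, summ$animal$timepoint), function(d) {
    if (length(unique(d$layer)) < 2L) return(NULL)
    fit <- stats::aov(mean_expression ~ layer, data = d)
    summary(fit)[[1L]][["Pr(>F)"]][1L]
  })
  dun <- twoWayAnovaDunnett(
    data.frame(value = summ$animal$mean_expression,
               layer = summ$animal$layer,
               timepoint = summ$animal$timepoint),
    reference = config$reference %||% "P1")
  report <- list(analysis = "fish",
                 mrna_threshold = thr,
                 layer_anova_p = layerAnova,
                 dunnett = dun$contrasts)
  out <- config$out %||% tempfile("fish-")
  writeRunArtifacts(out, config, report,
                    list(cells = cells, animal_means = summ$animal,
                         group_summary = summ$group,
                         dunnett_contrasts = dun$contrasts))
  invisible(list(cells = cells, summary = summ, layerAnova = layerAnova,
                 timepointDunnett = dun, out = out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
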