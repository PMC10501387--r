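#' Construct a FilamentTree from a node table
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z`, `radius`,
#'   `parent` (NA or -1 for the root) and optionally `type`.
#' @return a validated [FilamentTree-class] object.
#' @examples
#' nd <- data.frame(id = 1:3, x = c(0, 5, 5), y = c(0, 0, 5), z = 0,
#'                  radius = c(1, 0.5, 0.5), parent = c(NA, 1, 2))
#' filamentTree(nd)
#' @export
filamentTree <- function(nodes) {
  nodes <- as.data.frame(nodes)
  if (is.null(nodes$type)) nodes$type <- 3L
  nodes$parent[!is.na(nodes$parent) & nodes$parent == -1] <- NA_integer_
  nodes <- nodes[, c("id", "type", "x", "y", "z", "radius", "parent")]
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  rownames(nodes) <- NULL
  root <- nodes$id[is.na(nodes$parent)]
  if (length(root) != 1L)
    stop("tree must have exactly one root node (parent -1/NA); found ", length(root))
  new("FilamentTree", nodes = nodes, rootId = root)
}

#' @rdname filamentTree
#' @param x a FilamentTree.
#' @export
treeNodes <- function(x) x@nodes

#' @rdname filamentTree
#' @export
rootId <- function(x) x@rootId

#' Construct a ShollCurve
#'
#' @param step shell spacing in micrometres.
#' @param counts integer vector of counts at radii `step * seq_along(counts)`.
#' @param dimension 2 or 3.
#' @export
shollCurve <- function(step, counts, dimension = 3L) {
  new("ShollCurve", step = as.numeric(step),
      radii = step * seq_along(counts),
      counts = as.integer(counts), dimension = as.integer(dimension))
}

#' @rdname shollCurve
#' @param x a ShollCurve.
#' @export
shollRadii <- function(x) x@radii

#' @rdname shollCurve
#' @export
shollCounts <- function(x) x@counts

#' Construct an ImageStack
#'
#' @param data 2D or 3D numeric array, indexed `[y, x]` or `[y, x, z]`.
#' @param voxelSize voxel size in micrometres: either a named vector with
#'   `z`, `y`, `x` components or an unnamed length-3 vector in that order.
#' @param channel channel label.
#' @export
imageStack <- function(data, voxelSize, channel = "unnamed") {
  if (is.null(dim(data))) dim(data) <- c(length(data), 1L)
  if (is.null(names(voxelSize))) {
    stopifnot(length(voxelSize) == 3L)
    names(voxelSize) <- c("z", "y", "x")
  }
  new("ImageStack", data = data, voxelSize = voxelSize[c("z", "y", "x")],
      channel = as.character(channel))
}

#' @rdname imageStack
#' @param x an ImageStack.
#' @export
stackData <- function(x) x@data

#' @rdname imageStack
#' @export
voxelSize <- function(x) x@voxelSize

#' Physical volume of one voxel / area of one pixel
#'
#' @param x an ImageStack.
#' @return voxel volume in cubic micrometres for 3D data; pixel area in
#'   square micrometres for 2D data.
#' @export
voxelVolume <- function(x) {
  vs <- x@voxelSize
  if (length(dim(x@data)) == 3L) unname(vs["z"] * vs["y"] * vs["x"])
  else unname(vs["y"] * vs["x"])
}

#' @rdname punctaLabels
#' @export
punctaCount <- function(x) length(x@sizes)

#' Accessors for PunctaSet
#'
#' @param x a PunctaSet.
#' @export
punctaLabels <- function(x) x@labels

#' @rdname punctaLabels
#' @export
punctaSizes <- function(x) x@sizes

#' Construct a StudyDesign
#'
#' Defaults describe the developmental FISH layout: five cortical layers,
#' four timepoints, three animals per timepoint and three sections per
#' animal, one image per layer and section (180 images in total).
#'
#' @param layers,timepoints character vectors.
#' @param animalsPerTimepoint,sectionsPerAnimal integers.
#' @export
studyDesign <- function(layers = c("L1", "L2/3", "L4", "L5", "L6"),
                        timepoints = c("P1", "P7", "P14", "P21"),
                        animalsPerTimepoint = 3L,
                        sectionsPerAnimal = 3L) {
  new("StudyDesign", layers = layers, timepoints = timepoints,
      animalsPerTimepoint = as.integer(animalsPerTimepoint),
      sectionsPerAnimal = as.integer(sectionsPerAnimal))
}

#' Number of images implied by a StudyDesign
#'
#' @param design a StudyDesign.
#' @export
designSize <- function(design) {
  length(design@layers) * length(design@timepoints) *
    design@animalsPerTimepoint * design@sectionsPerAnimal
}

#' Expand a StudyDesign into its image manifest
#'
#' @param design a StudyDesign.
#' @return data.frame with one row per image: `image_id`, `timepoint`,
#'   `animal`, `section`, `layer`.
#' @export
designManifest <- function(design) {
  g <- expand.grid(layer = design@layers,
                   section = paste0("S", seq_len(design@sectionsPerAnimal)),
                   animalIdx = seq_len(design@animalsPerTimepoint),
                   timepoint = design@timepoints,
                   stringsAsFactors = FALSE)
  g$animal <- paste0(g$timepoint, "_A", g$animalIdx)
  g$animalIdx <- NULL
  g$image_id <- sprintf("img%03d", seq_len(nrow(g)))
  g[, c("image_id", "timepoint", "animal", "section", "layer")]
}
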