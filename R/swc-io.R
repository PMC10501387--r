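#' Read a filament reconstruction from an SWC file
#'
#' Parses the standard 7-column SWC format (id, type, x, y, z, radius,
#' parent; whitespace-delimited, `#` comments, parent -1 for the root).
#' Coordinates and radii are interpreted as micrometres.
#'
#' @param path path to an SWC file.
#' @return a validated [FilamentTree-class].
#' @seealso [writeSWC()]
#' @export
readSWC <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  lines <- sub("#.*$", "", lines)
  keep <- grepl("\\S", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L) stop("SWC parse error: no data lines in ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(toks) != 7L)
  if (length(bad) > 0L)
    stop("SWC parse error at line ", lineno[bad[1L]],
         ": expected 7 columns, found ", length(toks[[bad[1L]]]))
  m <- suppressWarnings(
    matrix(as.numeric(unlist(toks)), ncol = 7L, byrow = TRUE))
  nn <- which(!stats::complete.cases(m))
  if (length(nn) > 0L)
    stop("SWC parse error at line ", lineno[nn[1L]], ": non-numeric field")
  nodes <- data.frame(id = as.integer(m[, 1L]), type = as.integer(m[, 2L]),
                      x = m[, 3L], y = m[, 4L], z = m[, 5L],
                      radius = m[, 6L], parent = as.integer(m[, 7L]))
  dup <- which(duplicated(nodes$id))
  if (length(dup) > 0L)
    stop("SWC parse error at line ", lineno[dup[1L]], ": duplicate node id ",
         nodes$id[dup[1L]])
  roots <- which(nodes$parent == -1L)
  if (length(roots) == 0L)
    stop("SWC parse error: no root node (parent -1) in ", path)
  if (length(roots) > 1L)
    stop("SWC parse error at line ", lineno[roots[2L]],
         ": multiple root nodes (parent -1)")
  miss <- which(nodes$parent != -1L & !(nodes$parent %in% nodes$id))
  if (length(miss) > 0L)
    stop("SWC parse error at line ", lineno[miss[1L]], ": node ",
         nodes$id[miss[1L]], " lists missing parent ", nodes$parent[miss[1L]])
  tr <- tryCatch(filamentTree(nodes), error = function(e)
    stop("SWC parse error in ", path, ": ", conditionMessage(e), call. = FALSE))
  tr
}

#' Write a FilamentTree to an SWC file
#'
#' Coordinates and radii are written with 6 significant digits, which
#' round-trips bit-exactly through [readSWC()] at that precision.
#'
#' @param tree a FilamentTree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSWC <- function(tree, path) {
  nd <- treeNodes(tree)
  parent <- ifelse(is.na(nd$parent), -1L, nd$parent)
  fmt <- function(v) formatC(signif(v, 6), format = "g", digits = 6)
  out <- paste(nd$id, nd$type, fmt(nd$x), fmt(nd$y), fmt(nd$z),
               fmt(nd$radius), parent)
  writeLines(c("# SWC export (id type x y z radius parent), coordinates in um",
               out), path)
  invisible(path)
}
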