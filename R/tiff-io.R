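# TIFF exchange for image stacks. Voxel sizes come from the caller's
# acquisition metadata, never from TIFF tags (which are routinely wrong
# in exported microscopy files).

#' Read an image stack from a (multi-page) TIFF file
#'
#' @param path TIFF file; pages become z slices.
#' @param voxelSize named `c(z=,y=,x=)` voxel size in micrometres,
#'   supplied by the caller.
#' @param channel channel label.
#' @return an [ImageStack-class].
#' @export
readImageStack <- function(path, voxelSize, channel = "unnamed") {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF files requires the 'tiff' package")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1L] else p)
  dat <- if (length(pages) == 1L) pages[[1L]]
         else array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
  imageStack(dat, voxelSize, channel)
}

#' Write an image stack to a (multi-page) TIFF file
#'
#' Intensities are rescaled to the unit range required by the TIFF
#' writer; the scale factor is returned invisibly.
#'
#' @param stack an [ImageStack-class].
#' @param path output path.
#' @return invisibly, the intensity scale factor used.
#' @export
writeImageStack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing TIFF files requires the 'tiff' package")
  dat <- stackData(stack)
  sc <- max(dat, 1e-12)
  dat <- dat / sc
  pages <- if (length(dim(dat)) == 2L) list(dat)
           else lapply(seq_len(dim(dat)[3L]), function(k) dat[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(sc)
}
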