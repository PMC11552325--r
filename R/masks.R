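#' Construct a segmentation mask
#'
#' @param raster logical H x W matrix; TRUE marks mask pixels.
#' @param score mask confidence in \code{[0, 1]} (for promptable deep
#'   segmenters this is the predicted IoU; the reference segmenter always
#'   reports 1).
#' @param mask_id integer rank, assigned by \code{\link{postprocess_masks}}.
#' @return A \code{stroi_mask} object with fields \code{mask_id},
#'   \code{raster}, \code{score}, \code{area_px}.
#' @export
segment_mask <- function(raster, score = 1, mask_id = NA_integer_) {
  if (!is.matrix(raster) || !is.logical(raster))
    stopf("raster must be a logical matrix")
  area <- sum(raster)
  if (area == 0L) stopf("mask raster has no TRUE pixels")
  if (!is.finite(score) || score < 0 || score > 1)
    stopf("score must lie in [0, 1], got %s", format(score))
  structure(
    list(mask_id = as.integer(mask_id), raster = raster,
         score = as.numeric(score), area_px = as.integer(area)),
    class = "stroi_mask"
  )
}

#' Order raw masks into a ranked mask set
#'
#' Masks are numbered in descending order of pixel area, so mask 1 is
#' always the largest; ties keep their original (proposal) order. The
#' segmentation mode and the confidence threshold that produced the set
#' are recorded for the run manifest.
#'
#' @param masks list of \code{stroi_mask} (may be empty).
#' @param image_shape integer (H, W) all rasters must share.
#' @param mode \code{"everything"} or \code{"prompt"}.
#' @param threshold_used confidence threshold applied upstream.
#' @return A \code{stroi_maskset}: list with \code{masks} (re-identified
#'   1..n by rank), \code{mode}, \code{image_shape}, \code{threshold_used}.
#' @export
postprocess_masks <- function(masks, image_shape,
                              mode = c("everything", "prompt"),
                              threshold_used = 0) {
  mode <- match.arg(mode)
  image_shape <- as.integer(image_shape)
  for (m in masks) {
    if (!identical(dim(m$raster), image_shape))
      stopf("mask raster shape (%s) does not match image_shape (%s)",
            paste(dim(m$raster), collapse = "x"),
            paste(image_shape, collapse = "x"))
  }
  if (length(masks)) {
    areas <- vapply(masks, `[[`, 0L, "area_px")
    ord <- order(-areas, seq_along(masks))   # area desc, ties by input order
    masks <- masks[ord]
    for (i in seq_along(masks)) masks[[i]]$mask_id <- i
  }
  structure(
    list(masks = masks, mode = mode, image_shape = image_shape,
         threshold_used = threshold_used),
    class = "stroi_maskset"
  )
}

#' @export
print.stroi_maskset <- function(x, ...) {
  cat(sprintf("<stroi_maskset> %d masks (%s-mode, threshold %.3g) on %s image\n",
              length(x$masks), x$mode, x$threshold_used,
              paste(x$image_shape, collapse = " x ")))
  if (length(x$masks)) {
    areas <- vapply(x$masks, `[[`, 0L, "area_px")
    cat(sprintf("  areas: %s px\n",
                paste(utils::head(areas, 8), collapse = ", ")))
  }
  invisible(x)
}

#' @export
length.stroi_maskset <- function(x) length(x$masks)

mask_by_id <- function(maskset, id) {
  for (m in maskset$masks) if (m$mask_id == id) return(m)
  stopf("mask id %d not found in mask set (%d masks)", id, length(maskset$masks))
}

#' Save / load a mask archive
#'
#' Dense boolean rasters are kept in memory; on disk the set is stored as a
#' single compressed archive written at run time.
#'
#' @param maskset a \code{stroi_maskset}.
#' @param path archive path (conventionally \code{masks.rds}).
#' @export
save_maskset <- function(maskset, path) {
  saveRDS(maskset, path, compress = "gzip")
  invisible(path)
}

#' @rdname save_maskset
#' @export
load_maskset <- function(path) {
  ms <- readRDS(path)
  if (!inherits(ms, "stroi_maskset")) stopf("%s is not a mask archive", path)
  ms
}

#' Axis-aligned box prompt
#'
#' @param x0,y0,x1,y1 working-image pixel coordinates with
#'   \code{x0 < x1}, \code{y0 < y1}.
#' @return A \code{stroi_box} list.
#' @export
box_prompt <- function(x0, y0, x1, y1) {
  if (!(x0 < x1 && y0 < y1))
    stopf("box must satisfy x0 < x1 and y0 < y1 (got [%g,%g]x[%g,%g])",
          x0, x1, y0, y1)
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "stroi_box")
}

box_intersects_image <- function(box, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]
  box$x1 > 0 && box$y1 > 0 && box$x0 < W && box$y0 < H
}
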