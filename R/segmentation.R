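#' Segmentation backend contract
#'
#' A backend is a plain list describing what a segmenter can do and how to
#' call it; any promptable segmenter (including SAM-style deep models) can
#' be wrapped to this contract, and the pipeline only ever talks to it:
#' \describe{
#'   \item{name}{backend identifier.}
#'   \item{capabilities}{subset of \code{c("everything", "boxes")}.}
#'   \item{everything}{\code{function(image)} returning a list of
#'     \code{\link{segment_mask}}, each with a confidence score in [0, 1].}
#'   \item{from_boxes}{\code{function(image, boxes)} returning exactly one
#'     mask per box, in box order.}
#' }
#'
#' @param name backend identifier.
#' @param capabilities character vector.
#' @param everything,from_boxes functions implementing the two modes
#'   (either may be NULL when the capability is absent).
#' @return A \code{stroi_backend} object.
#' @export
segmenter_backend <- function(name, capabilities, everything = NULL,
                              from_boxes = NULL) {
  structure(list(name = name, capabilities = capabilities,
                 everything = everything, from_boxes = from_boxes),
            class = "stroi_backend")
}

#' @export
print.stroi_backend <- function(x, ...) {
  cat(sprintf("<stroi_backend> '%s' [%s]\n", x$name,
              paste(x$capabilities, collapse = ", ")))
  invisible(x)
}

#' Everything-mode segmentation
#'
#' Asks the backend for mask proposals over the whole image and keeps those
#' whose confidence score is at least \code{confidence_threshold}. Raising
#' the threshold makes the segmenter more stringent: the returned count is
#' non-increasing in the threshold for a fixed backend and image.
#'
#' @param backend a \code{\link{segmenter_backend}} with the
#'   \code{everything} capability.
#' @param image H x W x 3 RGB array.
#' @param confidence_threshold value in \code{[0, 1]}.
#' @return List of \code{stroi_mask} (unranked; pass to
#'   \code{\link{postprocess_masks}}).
#' @export
segment_everything <- function(backend, image, confidence_threshold = 0.5) {
  if (!("everything" %in% backend$capabilities))
    stopf("backend '%s' does not support everything-mode", backend$name)
  if (!is.finite(confidence_threshold) ||
      confidence_threshold < 0 || confidence_threshold > 1)
    stopf("confidence_threshold must lie in [0, 1], got %s",
          format(confidence_threshold))
  proposals <- backend$everything(image)
  keep <- vapply(proposals, function(m) m$score >= confidence_threshold,
                 TRUE)
  proposals[keep]
}

#' Prompt-mode segmentation from box prompts
#'
#' Returns exactly one mask per box, in box order. Boxes fully outside the
#' image are rejected with the offending index.
#'
#' @param backend a backend with the \code{boxes} capability.
#' @param image H x W x 3 RGB array.
#' @param boxes non-empty list of \code{\link{box_prompt}}.
#' @return List of \code{stroi_mask}, one per box.
#' @export
segment_boxes <- function(backend, image, boxes) {
  if (!("boxes" %in% backend$capabilities))
    stopf("backend '%s' does not support box prompts", backend$name)
  if (length(boxes) == 0L) stopf("boxes must be non-empty")
  shape <- dim(image)[1:2]
  for (i in seq_along(boxes)) {
    if (!inherits(boxes[[i]], "stroi_box"))
      boxes[[i]] <- do.call(box_prompt, as.list(boxes[[i]])[c("x0", "y0",
                                                              "x1", "y1")])
    if (!box_intersects_image(boxes[[i]], shape))
      stopf("box %d ([%g,%g]x[%g,%g]) lies fully outside the %s image",
            i, boxes[[i]]$x0, boxes[[i]]$x1, boxes[[i]]$y0, boxes[[i]]$y1,
            paste(shape, collapse = "x"))
  }
  masks <- backend$from_boxes(image, boxes)
  if (length(masks) != length(boxes))
    stopf("backend '%s' returned %d masks for %d boxes", backend$name,
          length(masks), length(boxes))
  masks
}

#' Deterministic colour-clustering reference segmenter
#'
#' A built-in backend so the whole workflow runs and is testable without
#' any deep-learning weights. Everything-mode clusters RGB pixels with
#' k-means (seeded, capped iterations), discards the background colour
#' class (the majority class along the image border) and turns each
#' 8-connected component of the remaining classes with at least
#' \code{min_area_px} pixels into a mask with confidence 1. Box mode keeps
#' the largest 8-connected component of non-background pixels inside the
#' box (falling back to the whole box region when the box contains only
#' background, so a box on a uniform image returns the box itself).
#'
#' @param k_colors number of colour clusters (>= 2; capped at the number
#'   of distinct colours present).
#' @param min_area_px minimum component area in pixels for everything-mode.
#' @param seed integer seed for k-means initialisation; the backend is a
#'   pure function of (image, parameters, seed).
#' @return A \code{\link{segmenter_backend}} with both capabilities.
#' @export
reference_segmenter <- function(k_colors = 4, min_area_px = 64, seed = 0) {
  if (k_colors < 2) stopf("k_colors must be >= 2")

  classify <- function(image) {
    d <- dim(image)
    if (d[1] < 2 || d[2] < 2) stopf("image must be at least 2 x 2 pixels")
    px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                as.vector(image[, , 3]))
    uniq <- unique(px)
    k <- min(k_colors, nrow(uniq))
    cl <- if (k == 1L) rep(1L, nrow(px)) else {
      km <- with_local_seed(seed,
        stats::kmeans(px, centers = k, iter.max = 25, nstart = 1))
      km$cluster
    }
    classes <- matrix(cl, nrow = d[1], ncol = d[2])
    border <- c(classes[1, ], classes[d[1], ], classes[, 1], classes[, d[2]])
    tab <- tabulate(border, nbins = k)
    background <- which(tab == max(tab))[1]   # ties -> lowest class index
    list(classes = classes, k = k, background = background)
  }

  segmenter_backend(
    name = "reference",
    capabilities = c("everything", "boxes"),
    everything = function(image) {
      cls <- classify(image)
      masks <- list()
      for (class_idx in seq_len(cls$k)) {
        if (class_idx == cls$background) next
        bin <- cls$classes == class_idx
        if (!any(bin)) next
        lab <- connected_components(bin)
        for (comp in seq_len(max(lab))) {
          raster <- lab == comp
          if (sum(raster) >= min_area_px)
            masks[[length(masks) + 1L]] <- segment_mask(raster, score = 1)
        }
      }
      masks
    },
    from_boxes = function(image, boxes) {
      cls <- classify(image)
      H <- dim(image)[1]; W <- dim(image)[2]
      lapply(boxes, function(b) {
        rows <- max(0L, round_half_up(b$y0)):min(H - 1L, round_half_up(b$y1))
        cols <- max(0L, round_half_up(b$x0)):min(W - 1L, round_half_up(b$x1))
        inbox <- matrix(FALSE, H, W)
        inbox[rows + 1L, cols + 1L] <- TRUE
        cand <- inbox & cls$classes != cls$background
        if (!any(cand)) cand <- inbox   # all-background box: return the box
        lab <- connected_components(cand)
        sizes <- tabulate(lab[lab > 0])
        segment_mask(lab == which.max(sizes), score = 1)
      })
    }
  )
}

#' Label 8-connected components of a binary mask
#'
#' Iterative minimum-label propagation over the 8-neighbourhood until a
#' fixed point; labels are then compacted to 1..n in order of first
#' appearance (row-major).
#'
#' @param bin logical matrix.
#' @return Integer matrix of the same shape: 0 for background, 1..n for
#'   components.
#' @export
connected_components <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0, H, W)
  lab[bin] <- which(bin)   # unique seed label per foreground pixel
  if (!any(bin)) return(matrix(0L, H, W))
  big <- Inf
  repeat {
    p <- matrix(big, H + 2L, W + 2L)
    p[2:(H + 1L), 2:(W + 1L)][bin] <- lab[bin]
    nb <- pmin(
      p[1:H,         2:(W + 1L)], p[3:(H + 2L), 2:(W + 1L)],
      p[2:(H + 1L),  1:W],        p[2:(H + 1L), 3:(W + 2L)],
      p[1:H,         1:W],        p[1:H,        3:(W + 2L)],
      p[3:(H + 2L),  1:W],        p[3:(H + 2L), 3:(W + 2L)]
    )
    new <- lab
    new[bin] <- pmin(lab[bin], nb[bin])
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- unique(as.vector(t(lab))[as.vector(t(bin))])  # row-major first touch
  out <- matrix(0L, H, W)
  out[bin] <- match(lab[bin], ids)
  out
}
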