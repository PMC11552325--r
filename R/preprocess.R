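#' Filter spots by total transcript count
#'
#' Removes spots outside the tissue and spots whose total raw transcript
#' count is strictly below \code{min_transcripts} (a spot with exactly the
#' threshold is retained: only spots with fewer transcripts are excluded).
#'
#' @param ds a \code{\link{spatial_dataset}} with raw counts.
#' @param min_transcripts minimum total transcripts per spot (default 200).
#' @return The dataset restricted to surviving spots.
#' @export
filter_spots <- function(ds, min_transcripts = 200) {
  totals <- Matrix::rowSums(ds$counts)
  keep <- ds$spot_table$in_tissue & totals >= min_transcripts
  if (!any(keep))
    stopf("all spots removed at min_transcripts = %g (max in-tissue total: %g)",
          min_transcripts,
          if (any(ds$spot_table$in_tissue))
            max(totals[ds$spot_table$in_tissue]) else 0)
  subset_spots(ds, which(keep))
}

#' Filter genes by detection
#'
#' Drops genes detected (count > 0) in fewer than \code{min_spots} spots.
#'
#' @param ds a \code{stroi_dataset}.
#' @param min_spots minimum number of spots a gene must be detected in
#'   (default 3).
#' @return The dataset restricted to surviving genes.
#' @export
filter_genes <- function(ds, min_spots = 3) {
  detected <- Matrix::colSums(ds$counts > 0)
  keep <- detected >= min_spots
  if (!any(keep))
    stopf("all genes removed at min_spots = %g", min_spots)
  ds$counts <- ds$counts[, keep, drop = FALSE]
  ds$gene_ids <- ds$gene_ids[keep]
  if (!is.null(ds$normalized))
    ds$normalized <- ds$normalized[, keep, drop = FALSE]
  ds
}

subset_spots <- function(ds, idx) {
  ds$counts <- ds$counts[idx, , drop = FALSE]
  ds$spot_table <- ds$spot_table[idx, , drop = FALSE]
  rownames(ds$spot_table) <- NULL
  if (!is.null(ds$normalized))
    ds$normalized <- ds$normalized[idx, , drop = FALSE]
  if (!is.null(ds$working_coords))
    ds$working_coords <- ds$working_coords[idx, , drop = FALSE]
  if (!is.null(ds$oob)) ds$oob <- ds$oob[idx]
  ds
}

#' Log-normalize counts per spot
#'
#' Scales each spot's counts to a common total and applies log1p:
#' \code{normalized[i, j] = ln(1 + counts[i, j] * target_sum / total_i)}.
#' Raw counts are retained unchanged alongside the normalized matrix.
#'
#' @param ds a filtered \code{stroi_dataset} (every spot total > 0).
#' @param target_sum per-spot total after scaling (default 1e4).
#' @return The dataset with \code{normalized} attached.
#' @export
lognormalize <- function(ds, target_sum = 1e4) {
  totals <- Matrix::rowSums(ds$counts)
  if (any(totals <= 0))
    stopf("%d spot(s) have zero total counts; run filter_spots first",
          sum(totals <= 0))
  scaled <- Matrix::Diagonal(x = target_sum / totals) %*% ds$counts
  norm <- methods::as(scaled, "CsparseMatrix")
  norm@x <- log1p(norm@x)
  ds$normalized <- norm
  ds
}

#' Align spot coordinates to the working image
#'
#' Full-resolution pixel coordinates are multiplied by the hires scale
#' factor so spots land on the working (hires) image; the spot diameter is
#' scaled the same way. Spots whose scaled coordinates fall outside the
#' image are flagged (and later labeled OTHER) with a warning.
#'
#' @param ds a \code{stroi_dataset} with an image attached.
#' @return The dataset with \code{working_coords} (data.frame x, y),
#'   \code{spot_diameter_px} and the out-of-bounds flag attached.
#' @export
align_coordinates <- function(ds) {
  s <- ds$scale$hires_scalef
  ds$working_coords <- data.frame(
    x = ds$spot_table$fullres_x * s,
    y = ds$spot_table$fullres_y * s
  )
  ds$spot_diameter_px <- ds$scale$spot_diameter_fullres * s
  ds <- flag_out_of_bounds(ds)
  ds
}

flag_out_of_bounds <- function(ds) {
  H <- dim(ds$image)[1]; W <- dim(ds$image)[2]
  wc <- ds$working_coords
  ds$oob <- wc$x < 0 | wc$x > W - 1 | wc$y < 0 | wc$y > H - 1
  bad <- ds$oob & ds$spot_table$in_tissue
  if (any(bad))
    warnf("%d in-tissue spot(s) fall outside the image and will be labeled OTHER (e.g. %s)",
          sum(bad), paste(utils::head(ds$spot_table$barcode[bad], 3),
                          collapse = ", "))
  ds
}

#' Crop the image to the tissue area
#'
#' Crops the working image to the bounding box of the in-tissue spot
#' coordinates, expanded by \code{pad} pixels on each side and clipped to
#' the image bounds, which drops the fiducial frame by geometry while
#' minimizing padding. All working coordinates are shifted by the returned
#' offset, which is also recorded on the dataset for the run manifest.
#' Degenerate windows are expanded to at least 2 x 2 pixels.
#'
#' @param ds a dataset with aligned working coordinates.
#' @param pad padding in working-image pixels; defaults to one working
#'   spot diameter.
#' @return The dataset with cropped image, shifted coordinates and
#'   \code{crop_offset = c(x, y)} recorded.
#' @export
crop_to_tissue <- function(ds, pad = NULL) {
  if (is.null(ds$working_coords))
    stopf("run align_coordinates before crop_to_tissue")
  pad <- pad %||% ds$spot_diameter_px
  it <- ds$spot_table$in_tissue
  if (!any(it)) stopf("no in-tissue spots to crop to")
  H <- dim(ds$image)[1]; W <- dim(ds$image)[2]
  wc <- ds$working_coords[it, , drop = FALSE]
  x0 <- max(0L, as.integer(floor(min(wc$x) - pad)))
  y0 <- max(0L, as.integer(floor(min(wc$y) - pad)))
  x1 <- min(W - 1L, as.integer(ceiling(max(wc$x) + pad)))
  y1 <- min(H - 1L, as.integer(ceiling(max(wc$y) + pad)))
  # degenerate windows get no area downstream; grow to >= 2x2
  if (x1 == x0) { if (x1 < W - 1L) x1 <- x1 + 1L else x0 <- x0 - 1L }
  if (y1 == y0) { if (y1 < H - 1L) y1 <- y1 + 1L else y0 <- y0 - 1L }

  ds$image <- ds$image[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L), ,
                       drop = FALSE]
  ds$working_coords$x <- ds$working_coords$x - x0
  ds$working_coords$y <- ds$working_coords$y - y0
  prev <- ds$crop_offset %||% c(0, 0)
  ds$crop_offset <- c(prev[1] + x0, prev[2] + y0)
  ds <- flag_out_of_bounds(ds)
  ds
}

#' 2 x 3 affine transform
#'
#' @param m 2 x 3 matrix \code{[[a, b, tx], [c, d, ty]]} mapping source
#'   \code{(x, y)} to image pixels. The linear part must be non-singular.
#' @return A \code{stroi_affine} object.
#' @export
affine_transform <- function(m) {
  m <- matrix(as.numeric(m), nrow = 2)
  if (ncol(m) != 3L) stopf("affine matrix must be 2 x 3")
  det <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (abs(det) <= 1e-12)
    stopf("affine linear part is singular (|det| = %.3g)", abs(det))
  structure(list(m = m, det = det), class = "stroi_affine")
}

#' Apply an affine transform to point coordinates
#'
#' Used to place imaging-based (e.g. Xenium) cell coordinates onto a
#' post-experiment image:
#' \code{(x', y') = (a x + b y + tx, c x + d y + ty)}. Points landing
#' outside the image are flagged, not dropped.
#'
#' @param coords data.frame or matrix with columns x, y.
#' @param t a \code{\link{affine_transform}}.
#' @param image_shape integer (H, W) used for the out-of-bounds flag.
#' @return data.frame with columns \code{x}, \code{y},
#'   \code{out_of_bounds}.
#' @export
apply_affine <- function(coords, t, image_shape) {
  if (!inherits(t, "stroi_affine")) t <- affine_transform(t)
  coords <- as.data.frame(coords)
  m <- t$m
  x <- m[1, 1] * coords$x + m[1, 2] * coords$y + m[1, 3]
  y <- m[2, 1] * coords$x + m[2, 2] * coords$y + m[2, 3]
  H <- image_shape[1]; W <- image_shape[2]
  data.frame(x = x, y = y,
             out_of_bounds = x < 0 | x > W - 1 | y < 0 | y > H - 1)
}
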