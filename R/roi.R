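#' Assign spots to the masks that contain them
#'
#' A spot belongs to every mask whose raster is TRUE at the spot's
#' rasterized working coordinate (round-half-up to the nearest pixel);
#' overlapping masks give multiple memberships. Spots flagged out of
#' bounds get no memberships.
#'
#' @param maskset a \code{\link{postprocess_masks}} result.
#' @param working_coords data.frame with columns x, y (0-based pixels).
#' @param oob optional logical vector flagging out-of-bounds spots.
#' @return A \code{stroi_assignment}: list with \code{containing} (per-spot
#'   integer vectors of mask ids), \code{oob}, and \code{label} (filled by
#'   \code{\link{build_roi}}).
#' @export
assign_spots <- function(maskset, working_coords, oob = NULL) {
  H <- maskset$image_shape[1]; W <- maskset$image_shape[2]
  n <- nrow(working_coords)
  px <- round_half_up(working_coords$x)
  py <- round_half_up(working_coords$y)
  oob <- (oob %||% rep(FALSE, n)) | px < 0 | px > W - 1 | py < 0 | py > H - 1
  lin <- ifelse(oob, NA_integer_, px * H + py + 1L)   # column-major index

  containing <- rep(list(integer(0)), n)
  inb <- which(!oob)
  if (length(inb)) {
    for (m in maskset$masks) {
      hit <- inb[m$raster[lin[inb]]]
      for (i in hit)
        containing[[i]] <- c(containing[[i]], m$mask_id)
    }
  }
  structure(list(containing = containing, oob = oob, label = NULL),
            class = "stroi_assignment")
}

#' Co-location proportion between a mask and the spot array
#'
#' Fraction of the mask's pixels that are covered by the union of spot
#' disks of the given diameter centred on the working coordinates. A pixel
#' (integer centre) is covered when its squared distance to some spot
#' centre is at most \code{(spot_diameter_px / 2)^2}.
#'
#' @param mask a \code{stroi_mask}.
#' @param working_coords data.frame of spot x, y.
#' @param spot_diameter_px spot disk diameter in working pixels (> 0).
#' @return Proportion in \code{[0, 1]}.
#' @export
colocation_proportion <- function(mask, working_coords, spot_diameter_px) {
  if (spot_diameter_px <= 0) stopf("spot_diameter_px must be > 0")
  covered <- spot_disk_union(dim(mask$raster), working_coords,
                             spot_diameter_px)
  sum(mask$raster & covered) / mask$area_px
}

# Boolean raster of the union of spot disks, built spot-by-spot over each
# disk's bounding window.
spot_disk_union <- function(shape, working_coords, spot_diameter_px) {
  H <- shape[1]; W <- shape[2]
  r <- spot_diameter_px / 2
  r2 <- r * r
  covered <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(working_coords))) {
    sx <- working_coords$x[i]; sy <- working_coords$y[i]
    xs <- max(0, ceiling(sx - r)):min(W - 1, floor(sx + r))
    ys <- max(0, ceiling(sy - r)):min(H - 1, floor(sy + r))
    if (xs[1] > xs[length(xs)] || ys[1] > ys[length(ys)]) next
    disk <- outer((ys - sy)^2, (xs - sx)^2, `+`) <= r2
    covered[ys + 1L, xs + 1L] <- covered[ys + 1L, xs + 1L] | disk
  }
  covered
}

#' Remove masks that do not co-locate with spots
#'
#' Everything-mode proposes masks over the whole image, including regions
#' with no spots (fiducials, empty glass). Masks whose co-location
#' proportion falls below \code{min_proportion} (default 0.01) are removed
#' and the survivors re-ranked by area.
#'
#' Two denominators are supported: \code{"mask-pixels"} (default; fraction
#' of mask pixels covered by spot disks, scale-free in mask size) and
#' \code{"spots-in-mask"} (fraction of all supplied spots whose centre
#' falls in the mask).
#'
#' @param maskset a ranked \code{stroi_maskset}.
#' @param working_coords spot coordinates (typically in-tissue only).
#' @param spot_diameter_px spot disk diameter in working pixels.
#' @param min_proportion removal threshold (default 0.01).
#' @param proportion_def \code{"mask-pixels"} or \code{"spots-in-mask"}.
#' @return A re-ranked \code{stroi_maskset} of the survivors (possibly
#'   empty, with a warning).
#' @export
filter_masks <- function(maskset, working_coords, spot_diameter_px,
                         min_proportion = 0.01,
                         proportion_def = c("mask-pixels", "spots-in-mask")) {
  proportion_def <- match.arg(proportion_def)
  if (length(maskset$masks) == 0L) return(maskset)
  props <- mask_proportions(maskset, working_coords, spot_diameter_px,
                            proportion_def)
  keep <- props >= min_proportion
  if (!any(keep))
    warnf("all %d masks fall below the co-location threshold %g",
          length(maskset$masks), min_proportion)
  postprocess_masks(maskset$masks[keep], maskset$image_shape,
                    mode = maskset$mode,
                    threshold_used = maskset$threshold_used)
}

mask_proportions <- function(maskset, working_coords, spot_diameter_px,
                             proportion_def = "mask-pixels") {
  if (proportion_def == "mask-pixels") {
    covered <- spot_disk_union(maskset$image_shape, working_coords,
                               spot_diameter_px)
    vapply(maskset$masks,
           function(m) sum(m$raster & covered) / m$area_px, 0)
  } else {
    H <- maskset$image_shape[1]; W <- maskset$image_shape[2]
    px <- round_half_up(working_coords$x)
    py <- round_half_up(working_coords$y)
    ok <- px >= 0 & px <= W - 1 & py >= 0 & py <= H - 1
    lin <- px[ok] * H + py[ok] + 1L
    n <- nrow(working_coords)
    vapply(maskset$masks,
           function(m) if (n == 0L) 0 else sum(m$raster[lin]) / n, 0)
  }
}

#' ROI selection
#'
#' Which mask ids form ROI 1 and (optionally) ROI 2. ROI 2 left empty
#' means a one-versus-others contrast downstream.
#'
#' @param roi1 non-empty integer vector of mask ids.
#' @param roi2 integer vector of mask ids (may be empty).
#' @return A \code{stroi_roi_selection}.
#' @export
roi_selection <- function(roi1, roi2 = integer(0)) {
  roi1 <- as.integer(roi1); roi2 <- as.integer(roi2)
  if (length(roi1) == 0L) stopf("ROI 1 must contain at least one mask")
  both <- intersect(roi1, roi2)
  if (length(both))
    stopf("mask id(s) %s appear in both ROIs", paste(both, collapse = ", "))
  structure(list(roi1 = unique(roi1), roi2 = unique(roi2)),
            class = "stroi_roi_selection")
}

#' Toggle the mask under a point in an ROI selection
#'
#' Click semantics for an interactive layer: among the masks containing
#' the point, the smallest-area one is toggled in the target ROI (added if
#' absent, removed if present — re-clicking deselects). Adding a mask to
#' one ROI removes it from the other. A point in no mask leaves the
#' selection unchanged and attaches a notice.
#'
#' @param maskset a \code{stroi_maskset}.
#' @param point numeric \code{c(x, y)} in working pixels.
#' @param current a \code{\link{roi_selection}}, or NULL for empty.
#' @param target_roi 1 or 2.
#' @return An updated selection (unclassed list with \code{roi1},
#'   \code{roi2}, and possibly \code{notice}).
#' @export
select_mask_at <- function(maskset, point, current = NULL, target_roi = 1) {
  cur <- list(roi1 = current$roi1 %||% integer(0),
              roi2 = current$roi2 %||% integer(0))
  H <- maskset$image_shape[1]; W <- maskset$image_shape[2]
  px <- round_half_up(point[1]); py <- round_half_up(point[2])
  if (px < 0 || px > W - 1 || py < 0 || py > H - 1)
    stopf("point (%g, %g) lies outside the image", point[1], point[2])
  hits <- Filter(function(m) m$raster[px * H + py + 1L], maskset$masks)
  if (length(hits) == 0L) {
    cur$notice <- "no mask at this point"
    return(structure(cur, class = "stroi_roi_selection"))
  }
  areas <- vapply(hits, `[[`, 0L, "area_px")
  id <- hits[[which.min(areas)]]$mask_id
  tgt <- if (target_roi == 1) "roi1" else "roi2"
  oth <- if (target_roi == 1) "roi2" else "roi1"
  if (id %in% cur[[tgt]]) {
    cur[[tgt]] <- setdiff(cur[[tgt]], id)
  } else {
    cur[[tgt]] <- c(cur[[tgt]], id)
    cur[[oth]] <- setdiff(cur[[oth]], id)
  }
  structure(cur, class = "stroi_roi_selection")
}

#' Label spots by ROI membership
#'
#' Turns mask memberships into the two-group contrast: a spot is ROI1 if
#' it lies in any ROI-1 mask, ROI2 if in any ROI-2 mask, EXCLUDED if in
#' masks of both ROIs (overlapping proposals are routine and exclusion
#' keeps the contrast clean), OTHER otherwise. When ROI 2 is left empty
#' the contrast is one-versus-others: every remaining in-tissue spot
#' becomes ROI2. Only in-tissue, in-bounds spots can carry ROI labels.
#'
#' @param selection a \code{\link{roi_selection}}.
#' @param assignment an \code{\link{assign_spots}} result.
#' @param in_tissue logical vector, one per spot.
#' @return The assignment with \code{label} filled (factor with levels
#'   ROI1, ROI2, OTHER, EXCLUDED).
#' @export
build_roi <- function(selection, assignment, in_tissue) {
  n <- length(assignment$containing)
  has1 <- vapply(assignment$containing,
                 function(ids) any(ids %in% selection$roi1), TRUE)
  has2 <- if (length(selection$roi2))
    vapply(assignment$containing,
           function(ids) any(ids %in% selection$roi2), TRUE)
  else rep(FALSE, n)

  eligible <- in_tissue & !assignment$oob
  label <- rep("OTHER", n)
  label[eligible & has1 & has2] <- "EXCLUDED"
  label[eligible & has1 & !has2] <- "ROI1"
  label[eligible & !has1 & has2] <- "ROI2"
  if (length(selection$roi2) == 0L)
    label[eligible & !has1 & !has2] <- "ROI2"   # one-vs-others

  n_ex <- sum(label == "EXCLUDED")
  if (n_ex) warnf("%d spot(s) lie in masks of both ROIs and are EXCLUDED", n_ex)
  if (sum(label == "ROI1") == 0L)
    stopf("ROI 1 contains no spots; select a mask containing spots")
  if (length(selection$roi2) && sum(label == "ROI2") == 0L)
    stopf("ROI 2 contains no spots; select a mask containing spots")

  assignment$label <- factor(label,
                             levels = c("ROI1", "ROI2", "OTHER", "EXCLUDED"))
  assignment
}

#' @export
print.stroi_assignment <- function(x, ...) {
  if (is.null(x$label)) {
    cat(sprintf("<stroi_assignment> %d spots, memberships only\n",
                length(x$containing)))
  } else {
    tb <- table(x$label)
    cat(sprintf("<stroi_assignment> %s\n",
                paste(sprintf("%s: %d", names(tb), tb), collapse = " | ")))
  }
  invisible(x)
}
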