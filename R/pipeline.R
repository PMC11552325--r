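#' Default pipeline configuration
#'
#' One flat record holding every tunable parameter of the workflow with
#' the published defaults: minimum 200 transcripts per spot, gene
#' detection in >= 3 spots, log-normalization target 1e4, co-location
#' cutoff 0.01, log2 fold-change cutoff 1, adjusted-p cutoff 0.05, top 10
#' genes, ORA reporting at adjusted p < 0.05.
#'
#' @param ... overrides for any field.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    config_version = 1L,
    bundle = NULL,            # dir with matrix/positions/scalefactors/image
    dataset = NULL,           # or an in-memory stroi_dataset
    min_transcripts = 200,
    min_spots_per_gene = 3,
    target_sum = 1e4,
    crop_pad = NULL,          # default: one working spot diameter
    backend = "reference",
    k_colors = 4,
    min_area_px = 64,
    seed = 0,
    mode = "everything",      # or "prompt"
    confidence_threshold = 0.5,
    boxes = NULL,             # prompt-mode: list of box_prompt / 4-vectors
    roi1 = NULL,              # everything-mode: mask ids
    roi2 = NULL,
    min_proportion = 0.01,
    proportion_def = "mask-pixels",
    logfc_cutoff = 1,
    padj_cutoff = 0.05,
    top_n = 10,
    gmt = NULL,               # paths or stroi_gene_sets (possibly a list)
    fractions = NULL,         # CSV path or matrix/data.frame
    overlay_opacity = 0.5,
    out = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the full image-guided ROI analysis pipeline
#'
#' Orchestrates \code{preprocess -> segment -> roi -> analyze}: reads (or
#' takes) the dataset, filters spots and genes, log-normalizes, aligns and
#' crops, segments the image through the configured backend, filters
#' everything-mode masks by spot co-location, builds the ROI contrast,
#' and runs Wilcoxon differential expression, over-representation
#' analysis per gene-set library, and cell-type proportion comparison.
#' The pipeline is a pure function of (inputs, config): stochastic stages
#' are seeded from \code{config$seed}.
#'
#' @param config a \code{\link{pipeline_config}}. Exactly one of
#'   \code{roi1} (everything-mode mask ids) or \code{boxes} (prompt-mode)
#'   must be supplied. In prompt-mode every box mask enters ROI 1 unless
#'   \code{roi1}/\code{roi2} index the boxes explicitly.
#' @return List with \code{dataset}, \code{maskset}, \code{selection},
#'   \code{assignment}, \code{degs}, \code{top} (per-ROI top gene lists),
#'   \code{ora} (named list per library), \code{proportions},
#'   \code{overlay}, and \code{manifest}. When \code{config$out} is set,
#'   all tables plus overlay PNG, mask archive and manifest JSON are also
#'   written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("[%s] %s", name, conditionMessage(e)))
  }
  prompt_mode <- identical(config$mode, "prompt")
  if (prompt_mode) {
    if (is.null(config$boxes))
      stopf("prompt-mode requires box prompts in config$boxes")
  } else if (is.null(config$roi1)) {
    stopf(paste0("no ROI specified: set config$roi1 (everything-mode mask ",
                 "ids) or config$mode = \"prompt\" with config$boxes"))
  }

  ds <- stage("load", {
    if (!is.null(config$dataset)) config$dataset
    else if (!is.null(config$bundle)) read_bundle_dir(config$bundle)
    else stopf("config must supply either a dataset or a bundle directory")
  })

  log_line <- function(...) message(sprintf(...))
  n0 <- nrow(ds$counts)
  ds <- stage("preprocess", {
    ds <- filter_spots(ds, config$min_transcripts)
    ds <- filter_genes(ds, config$min_spots_per_gene)
    ds <- lognormalize(ds, config$target_sum)
    ds <- align_coordinates(ds)
    crop_to_tissue(ds, pad = config$crop_pad)
  })
  log_line("preprocess: %d/%d spots kept, %d genes, image %s",
           nrow(ds$counts), n0, length(ds$gene_ids),
           paste(dim(ds$image)[1:2], collapse = "x"))

  backend <- stage("segment", {
    if (inherits(config$backend, "stroi_backend")) config$backend
    else if (identical(config$backend, "reference"))
      reference_segmenter(k_colors = config$k_colors,
                          min_area_px = config$min_area_px,
                          seed = config$seed)
    else stopf("unknown backend '%s'", config$backend)
  })

  maskset <- stage("segment", {
    if (prompt_mode) {
      boxes <- lapply(config$boxes, function(b)
        if (inherits(b, "stroi_box")) b else
          box_prompt(b[[1]], b[[2]], b[[3]], b[[4]]))
      raw <- segment_boxes(backend, ds$image, boxes)
      postprocess_masks(raw, dim(ds$image)[1:2], mode = "prompt")
    } else {
      raw <- segment_everything(backend, ds$image,
                                config$confidence_threshold)
      ms <- postprocess_masks(raw, dim(ds$image)[1:2], mode = "everything",
                              threshold_used = config$confidence_threshold)
      it <- ds$spot_table$in_tissue & !ds$oob
      filter_masks(ms, ds$working_coords[it, , drop = FALSE],
                   ds$spot_diameter_px,
                   min_proportion = config$min_proportion,
                   proportion_def = config$proportion_def)
    }
  })
  log_line("segment (%s): %d masks kept", maskset$mode, length(maskset$masks))
  if (length(maskset$masks) == 0L)
    stopf("[segment] no masks survive; lower the confidence threshold or min_area_px")

  selection <- stage("roi", {
    if (prompt_mode && is.null(config$roi1)) {
      # prompt boxes are the ROIs: every box mask goes to ROI 1
      roi_selection(vapply(maskset$masks, `[[`, 0L, "mask_id"))
    } else {
      roi_selection(config$roi1, config$roi2 %||% integer(0))
    }
  })
  assignment <- stage("roi", {
    a <- assign_spots(maskset, ds$working_coords, oob = ds$oob)
    build_roi(selection, a, ds$spot_table$in_tissue)
  })
  lb <- table(assignment$label)
  log_line("roi: ROI1 %d | ROI2 %d | other %d | excluded %d spots",
           lb[["ROI1"]], lb[["ROI2"]], lb[["OTHER"]], lb[["EXCLUDED"]])

  degs <- stage("analyze", {
    d <- wilcoxon_deg(ds, assignment)
    classify_degs(d, config$logfc_cutoff, config$padj_cutoff)
  })
  top <- list(roi1 = top_degs(degs, config$top_n, roi = 1),
              roi2 = top_degs(degs, config$top_n, roi = 2))
  log_line("analyze: %d up in ROI1, %d up in ROI2 (of %d genes)",
           sum(degs$group == "up_roi1"), sum(degs$group == "up_roi2"),
           nrow(degs))

  libraries <- stage("analyze", load_libraries(config$gmt))
  ora_tabs <- list()
  for (lib in libraries) {
    up1 <- degs$gene[degs$group == "up_roi1"]
    ora_tabs[[lib$name]] <- if (length(up1))
      ora(up1, lib, ds$gene_ids, padj_keep = config$padj_cutoff) else NULL
    up2 <- degs$gene[degs$group == "up_roi2"]
    ora_tabs[[paste0(lib$name, "_roi2")]] <- if (length(up2))
      ora(up2, lib, ds$gene_ids, padj_keep = config$padj_cutoff) else NULL
  }
  ora_tabs <- ora_tabs[!vapply(ora_tabs, is.null, TRUE)]

  props <- stage("analyze", {
    fr <- config$fractions
    if (is.null(fr)) NULL
    else {
      if (is.character(fr)) fr <- utils::read.csv(fr, check.names = FALSE)
      celltype_proportions(fr, assignment,
                           barcodes = ds$spot_table$barcode)
    }
  })

  overlay <- render_overlay(ds$image, maskset, selection,
                            opacity = config$overlay_opacity)

  manifest <- list(
    package_version = as.character(utils::packageVersion("stroi")),
    parameters = config[setdiff(names(config), c("dataset", "backend",
                                                 "gmt", "fractions",
                                                 "boxes"))],
    boxes = if (prompt_mode) lapply(config$boxes, unlist) else NULL,
    backend = backend$name,
    libraries = vapply(libraries, `[[`, "", "name"),
    crop_offset = ds$crop_offset,
    n_spots = nrow(ds$counts),
    n_genes = length(ds$gene_ids),
    n_masks = length(maskset$masks),
    labels = as.list(table(assignment$label)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  res <- list(dataset = ds, maskset = maskset, selection = selection,
              assignment = assignment, degs = degs, top = top,
              ora = ora_tabs, proportions = props, overlay = overlay,
              manifest = manifest)
  if (!is.null(config$out))
    write_results(degs, ora_tabs, props, config$out, manifest = manifest,
                  assignment = assignment,
                  barcodes = ds$spot_table$barcode,
                  maskset = maskset, overlay = overlay)
  res
}

# Resolve a bundle directory into the four component paths.
read_bundle_dir <- function(dir) {
  if (!dir.exists(dir)) stopf("bundle directory does not exist: %s", dir)
  pick <- function(pats, what) {
    for (p in pats) {
      hit <- list.files(dir, pattern = p, full.names = TRUE)
      if (length(hit)) return(hit[1])
    }
    stopf("no %s found in %s", what, dir)
  }
  positions <- pick(c("^tissue_positions.*\\.csv$"), "positions CSV")
  scalef <- pick(c("^scalefactors.*\\.json$"), "scalefactors JSON")
  image <- pick(c("\\.png$", "\\.tiff?$", "\\.jpe?g$"), "tissue image")
  matrix_path <- {
    h5 <- list.files(dir, pattern = "\\.h5$", full.names = TRUE)
    if (length(h5)) h5[1] else dir
  }
  read_visium_bundle(matrix_path, positions, scalef, image)
}

load_libraries <- function(gmt) {
  if (is.null(gmt)) return(list())
  if (inherits(gmt, "stroi_gene_sets")) return(list(gmt))
  if (is.character(gmt)) return(lapply(gmt, read_gmt))
  if (is.list(gmt)) return(gmt)
  stopf("config$gmt must be GMT paths or gene-set libraries")
}

#' Render a mask overlay image
#'
#' Alpha-blends a deterministic per-mask tint over the tissue image:
#' \code{out = (1 - opacity) * image + opacity * tint}, rounded to 8 bits,
#' with the tint cycling through a fixed 10-colour palette by mask id.
#' Masks selected in either ROI are outlined (ROI 1 white, ROI 2 black).
#'
#' @param image H x W x 3 array (0..255).
#' @param maskset a \code{stroi_maskset}.
#' @param selection optional \code{\link{roi_selection}} to outline.
#' @param opacity tint opacity in \code{[0, 1]}.
#' @return H x W x 3 integer array.
#' @export
render_overlay <- function(image, maskset, selection = NULL, opacity = 0.5) {
  if (opacity < 0 || opacity > 1) stopf("opacity must lie in [0, 1]")
  pal <- stroi_palette()
  out <- image * 1.0
  for (m in maskset$masks) {
    tint <- pal[(m$mask_id - 1L) %% nrow(pal) + 1L, ]
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[m$raster] <- (1 - opacity) * plane[m$raster] + opacity * tint[ch]
      out[, , ch] <- plane
    }
  }
  if (!is.null(selection)) {
    for (m in maskset$masks) {
      col <- if (m$mask_id %in% selection$roi1) 255
             else if (m$mask_id %in% selection$roi2) 0
             else next
      edge <- mask_outline(m$raster)
      for (ch in 1:3) {
        plane <- out[, , ch]
        plane[edge] <- col
        out[, , ch] <- plane
      }
    }
  }
  out <- round(out)
  storage.mode(out) <- "integer"
  out
}

# Mask pixels with at least one 4-neighbour outside the mask.
mask_outline <- function(raster) {
  H <- nrow(raster); W <- ncol(raster)
  p <- matrix(FALSE, H + 2L, W + 2L)
  p[2:(H + 1L), 2:(W + 1L)] <- raster
  interior <- p[1:H, 2:(W + 1L)] & p[3:(H + 2L), 2:(W + 1L)] &
    p[2:(H + 1L), 1:W] & p[2:(H + 1L), 3:(W + 2L)]
  raster & !interior
}

#' Write result tables, overlay and run manifest
#'
#' CSVs are written with a stable column order and full double precision
#' (17 significant digits), so reading them back reproduces the values
#' exactly; the JSON manifest records every run parameter.
#'
#' @param degs DEG table (may have zero rows).
#' @param ora_tabs named list of ORA tables (may be empty).
#' @param props \code{stroi_proportions} or NULL.
#' @param outdir output directory (created).
#' @param manifest named list of run metadata/parameters.
#' @param assignment,barcodes optional labeled assignment to write
#'   \code{labels.csv}.
#' @param maskset,overlay optional mask archive and overlay image.
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(degs, ora_tabs = list(), props = NULL, outdir,
                          manifest = list(), assignment = NULL,
                          barcodes = NULL, maskset = NULL, overlay = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put <- function(df, name) {
    path <- file.path(outdir, name)
    write_csv_exact(df, path)
    written <<- c(written, path)
  }

  put(degs[, c("gene", "log_fc", "p_value", "p_adj", "mean_roi1",
               "mean_roi2", "group"), drop = FALSE], "degs.csv")
  for (nm in names(ora_tabs))
    put(ora_tabs[[nm]][, c("term", "k", "K", "n", "N", "p_value", "p_adj",
                           "reported"), drop = FALSE],
        sprintf("ora_%s.csv", nm))
  if (!is.null(props)) {
    pr <- data.frame(cell_type = colnames(props$roi_means),
                     mean_roi1 = props$roi_means["ROI1", ],
                     mean_roi2 = props$roi_means["ROI2", ],
                     row.names = NULL)
    put(pr, "proportions.csv")
  }
  if (!is.null(assignment) && !is.null(assignment$label)) {
    lab <- data.frame(
      barcode = barcodes %||% seq_along(assignment$label),
      label = as.character(assignment$label),
      containing_mask_ids = vapply(assignment$containing,
                                   paste, "", collapse = ";"),
      row.names = NULL
    )
    put(lab, "labels.csv")
  }
  if (!is.null(maskset)) {
    save_maskset(maskset, file.path(outdir, "masks.rds"))
    written <- c(written, file.path(outdir, "masks.rds"))
  }
  if (!is.null(overlay)) {
    write_rgb_image(overlay, file.path(outdir, "overlay.png"))
    written <- c(written, file.path(outdir, "overlay.png"))
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  written <- c(written, file.path(outdir, "manifest.json"))
  invisible(written)
}

# CSV writer preserving doubles exactly (round-trips at 1e-12 and better).
write_csv_exact <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.double(df2[[j]])) df2[[j]] <- sprintf("%.17g", df2[[j]])
  }
  utils::write.csv(df2, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a written DEG table
#' @param path \code{degs.csv} produced by \code{\link{write_results}}.
#' @return data.frame with numeric columns restored.
#' @export
read_deg_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("log_fc", "p_value", "p_adj", "mean_roi1", "mean_roi2"))
    df[[col]] <- as.numeric(df[[col]])
  df
}
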