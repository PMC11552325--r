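#' Construct a spatial transcriptomics dataset
#'
#' The central container every stage of the workflow transforms: a raw
#' spot-by-gene count matrix, the per-spot position table, the platform
#' scale factors, and the tissue image. Normalized expression, working-image
#' coordinates and the crop offset are attached by the preprocessing steps.
#'
#' Coordinate convention: pixel coordinates are 0-based with
#' \code{(x, y) = (column, row)}; \code{fullres_x}/\code{fullres_y} are
#' full-resolution image pixels, and working-image coordinates are obtained
#' by multiplying with \code{scale$hires_scalef}.
#'
#' @param counts non-negative integer matrix (dense or \pkg{Matrix} sparse),
#'   spots in rows, genes in columns.
#' @param gene_ids character vector of unique gene symbols, one per column.
#' @param spot_table data.frame with columns \code{barcode},
#'   \code{in_tissue} (logical), \code{fullres_x}, \code{fullres_y}.
#' @param scale list with \code{hires_scalef} and \code{spot_diameter_fullres},
#'   both strictly positive.
#' @param image RGB raster: H x W x 3 array of 8-bit values in 0..255.
#' @param normalized optional normalized expression matrix, same shape as
#'   \code{counts}.
#' @return An object of class \code{stroi_dataset}.
#' @export
spatial_dataset <- function(counts, gene_ids, spot_table, scale, image,
                            normalized = NULL) {
  ds <- structure(
    list(
      counts = counts,
      gene_ids = as.character(gene_ids),
      spot_table = spot_table,
      scale = scale,
      image = image,
      normalized = normalized,
      working_coords = NULL,
      spot_diameter_px = NULL,
      crop_offset = NULL,
      oob = NULL
    ),
    class = "stroi_dataset"
  )
  validate_spatial_dataset(ds)
  ds
}

validate_spatial_dataset <- function(ds) {
  if (nrow(ds$counts) != nrow(ds$spot_table))
    stopf("counts has %d spots but spot_table has %d rows",
          nrow(ds$counts), nrow(ds$spot_table))
  if (ncol(ds$counts) != length(ds$gene_ids))
    stopf("counts has %d genes but gene_ids has length %d",
          ncol(ds$counts), length(ds$gene_ids))
  if (anyDuplicated(ds$gene_ids))
    stopf("gene_ids must be unique (%d duplicates)",
          sum(duplicated(ds$gene_ids)))
  req <- c("barcode", "in_tissue", "fullres_x", "fullres_y")
  miss <- setdiff(req, names(ds$spot_table))
  if (length(miss))
    stopf("spot_table missing column(s): %s", paste(miss, collapse = ", "))
  xy <- c(ds$spot_table$fullres_x, ds$spot_table$fullres_y)
  if (length(xy) && (any(!is.finite(xy)) || any(xy < 0)))
    stopf("fullres coordinates must be finite and >= 0")
  if (!is.null(ds$scale)) {
    if (!(ds$scale$hires_scalef > 0) || !(ds$scale$spot_diameter_fullres > 0))
      stopf("scale factors must be strictly positive")
  }
  if (!is.null(ds$image)) {
    d <- dim(ds$image)
    if (length(d) != 3L || d[3] != 3L)
      stopf("image must be an H x W x 3 array")
  }
  if (!is.null(ds$normalized) &&
      !identical(dim(ds$normalized), dim(ds$counts)))
    stopf("normalized matrix must have the same shape as counts")
  invisible(ds)
}

#' @export
print.stroi_dataset <- function(x, ...) {
  cat(sprintf("<stroi_dataset> %d spots x %d genes\n",
              nrow(x$counts), length(x$gene_ids)))
  cat(sprintf("  in tissue: %d | image: %s | normalized: %s\n",
              sum(x$spot_table$in_tissue),
              if (is.null(x$image)) "none"
              else paste(dim(x$image)[1:2], collapse = " x "),
              if (is.null(x$normalized)) "no" else "yes"))
  if (!is.null(x$working_coords))
    cat(sprintf("  working coords present (spot diameter %.2f px%s)\n",
                x$spot_diameter_px,
                if (is.null(x$crop_offset)) ""
                else sprintf(", crop offset (%g, %g)",
                             x$crop_offset[1], x$crop_offset[2])))
  invisible(x)
}

#' Read a Visium-style spatial transcriptomics bundle
#'
#' Assembles a \code{\link{spatial_dataset}} from the standard Space Ranger
#' style layout: a feature-barcode count matrix (MTX triplet directory or a
#' 10x HDF5 file), a tissue positions table (both the header and headerless
#' CSV dialects are accepted), a scale-factors JSON record, and the tissue
#' image (PNG, TIFF or JPEG).
#'
#' Duplicated gene symbols are made unique with a numeric suffix
#' (second copy of \code{"ACTB"} becomes \code{"ACTB_2"}). Barcodes present
#' in the matrix but absent from the positions table are always a hard
#' error; positions rows whose barcode is absent from the matrix are an
#' error by default (\code{extra_positions = "error"}) or silently dropped
#' with \code{extra_positions = "drop"} for bundles that ship positions for
#' every array spot alongside a filtered matrix.
#'
#' @param matrix_path directory containing \code{matrix.mtx},
#'   \code{features.tsv}/\code{genes.tsv} and \code{barcodes.tsv}
#'   (optionally gzipped), a path to a \code{matrix.mtx} file in such a
#'   directory, or a 10x HDF5 (\code{.h5}) feature-barcode matrix.
#' @param positions_path tissue positions CSV (barcode, in_tissue,
#'   array_row, array_col, pxl_row_in_fullres, pxl_col_in_fullres).
#' @param scalefactors_path scale-factors JSON with
#'   \code{tissue_hires_scalef} and \code{spot_diameter_fullres}.
#' @param image_path tissue image (the working/hires image the scale factor
#'   maps to).
#' @param extra_positions \code{"error"} or \code{"drop"}; see Details.
#' @return A \code{stroi_dataset} whose spot table is aligned 1:1 with the
#'   matrix rows.
#' @export
read_visium_bundle <- function(matrix_path, positions_path,
                               scalefactors_path, image_path,
                               extra_positions = c("error", "drop")) {
  extra_positions <- match.arg(extra_positions)
  for (p in c(matrix_path, positions_path, scalefactors_path, image_path))
    if (!file.exists(p)) stopf("path does not exist: %s", p)

  cm <- read_count_matrix(matrix_path)   # list(counts spots x genes, barcodes, symbols)
  pos <- read_tissue_positions(positions_path)

  missing_bc <- setdiff(cm$barcodes, pos$barcode)
  if (length(missing_bc))
    stopf(paste0("barcode mismatch: %d of %d matrix barcodes absent from ",
                 "positions (%d positions rows); first missing: %s"),
          length(missing_bc), length(cm$barcodes), nrow(pos), missing_bc[1])
  extra_bc <- setdiff(pos$barcode, cm$barcodes)
  if (length(extra_bc)) {
    if (extra_positions == "error")
      stopf(paste0("positions contain %d barcode(s) absent from the matrix ",
                   "(first: %s); pass extra_positions = \"drop\" to ignore"),
            length(extra_bc), extra_bc[1])
    pos <- pos[pos$barcode %in% cm$barcodes, , drop = FALSE]
  }
  pos <- pos[match(cm$barcodes, pos$barcode), , drop = FALSE]
  rownames(pos) <- NULL

  scale <- read_scalefactors(scalefactors_path)
  image <- read_rgb_image(image_path)

  spatial_dataset(
    counts = cm$counts,
    gene_ids = dedup_suffix(cm$symbols),
    spot_table = data.frame(
      barcode = pos$barcode,
      in_tissue = as.logical(pos$in_tissue),
      fullres_x = as.numeric(pos$pxl_col_in_fullres),
      fullres_y = as.numeric(pos$pxl_row_in_fullres),
      stringsAsFactors = FALSE
    ),
    scale = scale,
    image = image
  )
}

# Reads MTX triplet dir or 10x HDF5; returns spots x genes sparse counts.
read_count_matrix <- function(path) {
  if (grepl("\\.h5$", path, ignore.case = TRUE))
    return(read_count_matrix_h5(path))
  dir <- if (dir.exists(path)) path else dirname(path)
  find1 <- function(cands) {
    for (f in cands) {
      p <- file.path(dir, f)
      if (file.exists(p)) return(p)
    }
    stopf("none of [%s] found in %s", paste(cands, collapse = ", "), dir)
  }
  mtx <- find1(c("matrix.mtx", "matrix.mtx.gz"))
  feat <- find1(c("features.tsv", "features.tsv.gz",
                  "genes.tsv", "genes.tsv.gz"))
  bc <- find1(c("barcodes.tsv", "barcodes.tsv.gz"))

  m <- Matrix::readMM(mtx)                        # genes x barcodes
  features <- utils::read.delim(feat, header = FALSE,
                                stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(bc, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(features) != nrow(m))
    stopf("features file has %d rows but matrix has %d genes",
          nrow(features), nrow(m))
  if (length(barcodes) != ncol(m))
    stopf("barcodes file has %d rows but matrix has %d columns",
          length(barcodes), ncol(m))
  symbols <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  list(counts = methods::as(Matrix::t(m), "CsparseMatrix"),
       barcodes = barcodes, symbols = as.character(symbols))
}

read_count_matrix_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stopf("reading 10x HDF5 matrices requires the 'rhdf5' package")
  root <- rhdf5::h5ls(path, recursive = FALSE)$name[1]
  g <- function(n) rhdf5::h5read(path, paste0(root, "/", n))
  shape <- as.integer(g("shape"))
  m <- Matrix::sparseMatrix(
    i = as.integer(g("indices")) + 1L,
    p = as.integer(g("indptr")),
    x = as.numeric(g("data")),
    dims = shape
  )                                                # genes x barcodes (CSC)
  symbols <- tryCatch(as.character(g("features/name")),
                      error = function(e) as.character(g("gene_names")))
  barcodes <- as.character(g("barcodes"))
  list(counts = methods::as(Matrix::t(m), "CsparseMatrix"),
       barcodes = barcodes, symbols = symbols)
}

# Both Space Ranger dialects: with header (tissue_positions.csv) or
# headerless (tissue_positions_list.csv); same six columns either way.
read_tissue_positions <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  cols <- c("barcode", "in_tissue", "array_row", "array_col",
            "pxl_row_in_fullres", "pxl_col_in_fullres")
  pos <- utils::read.csv(path, header = has_header,
                         stringsAsFactors = FALSE)
  if (ncol(pos) < 6L)
    stopf("positions file has %d columns; expected 6", ncol(pos))
  names(pos)[1:6] <- cols
  pos
}

read_scalefactors <- function(path) {
  sf <- jsonlite::fromJSON(path)
  hires <- sf$tissue_hires_scalef %||% sf$hires_scalef
  diam <- sf$spot_diameter_fullres
  if (is.null(hires) || is.null(diam))
    stopf("scalefactors JSON must contain tissue_hires_scalef and spot_diameter_fullres")
  list(hires_scalef = as.numeric(hires),
       spot_diameter_fullres = as.numeric(diam))
}

#' Read an image file as an 8-bit RGB array
#'
#' @param path PNG, TIFF or JPEG file.
#' @return H x W x 3 integer array with values in 0..255. Grayscale images
#'   are replicated across channels; an alpha channel is dropped.
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(
    ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stopf("reading TIFF images requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stopf("reading JPEG images requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stopf("unreadable image (unsupported extension '%s'): %s", ext, path)
  )
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  arr <- round(img * 255)
  storage.mode(arr) <- "integer"
  arr
}

#' Write an 8-bit RGB array to PNG
#' @param image H x W x 3 array, values 0..255.
#' @param path output file.
#' @export
write_rgb_image <- function(image, path) {
  png::writePNG(image / 255, target = path)
  invisible(path)
}
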