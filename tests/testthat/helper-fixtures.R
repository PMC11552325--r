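# In-code fixture builders shared by the tests.

# Minimal dataset: given a counts matrix (spots x genes), wrap it with a
# plain image and unit scale factors so preprocessing functions can run.
tiny_dataset <- function(counts, in_tissue = rep(TRUE, nrow(counts)),
                         fullres_x = seq_len(nrow(counts)) * 2,
                         fullres_y = seq_len(nrow(counts)) * 2,
                         hires_scalef = 1, spot_diameter_fullres = 2,
                         image_hw = c(64, 64)) {
  counts <- as.matrix(counts)
  spatial_dataset(
    counts = counts,
    gene_ids = colnames(counts) %||% sprintf("G%03d", seq_len(ncol(counts))),
    spot_table = data.frame(
      barcode = sprintf("BC-%03d", seq_len(nrow(counts))),
      in_tissue = in_tissue,
      fullres_x = fullres_x, fullres_y = fullres_y,
      stringsAsFactors = FALSE
    ),
    scale = list(hires_scalef = hires_scalef,
                 spot_diameter_fullres = spot_diameter_fullres),
    image = array(255L, dim = c(image_hw, 3L))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small planted two-region fixture spec that keeps unit tests fast.
small_fixture_spec <- function(seed = 7, ...) {
  fixture_spec(
    image_shape = c(80L, 80L),
    regions = list(
      list(shape = "rectangle", geometry = c(8, 8, 34, 60),
           color = c(200L, 60L, 60L)),
      list(shape = "rectangle", geometry = c(46, 12, 72, 66),
           color = c(60L, 90L, 200L))
    ),
    spot_pitch = 5,
    n_genes = 120,
    markers_per_region = 5,
    n_decoy_terms = 8,
    seed = seed,
    ...
  )
}

# Rectangle mask raster on an H x W canvas (0-based inclusive pixel bounds).
rect_mask <- function(shape, x0, y0, x1, y1, score = 1) {
  r <- matrix(FALSE, shape[1], shape[2])
  r[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <- TRUE
  segment_mask(r, score = score)
}

# Labelled-membership oracle comparison helper: two labelings agree as
# partitions when the label pairs are in bijection.
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  key <- paste(a[a > 0], b[b > 0])
  length(unique(key)) == length(unique(a[a > 0])) &&
    length(unique(key)) == length(unique(b[b > 0]))
}
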