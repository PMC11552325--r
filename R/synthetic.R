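#' Specification for a synthetic Visium-style fixture
#'
#' Defines the planted-truth conditions every stage of the workflow is
#' exercised under: a white tissue image carrying solid-colour regions, a
#' square spot lattice, negative-binomial counts (spatial counts are
#' overdispersed, so Poisson would be too kind to the test) with marker
#' genes up-regulated inside their region, a planted gene-set library with
#' decoy terms, and per-region Dirichlet cell-type profiles.
#'
#' Defaults give two well-separated rectangular regions on a 200 x 200
#' image with ~2 px spot pitch coverage: ~440 in-tissue spots, 2000 genes,
#' 10 markers per region at log2 fold change 2 over a baseline mean of 0.5
#' counts per gene (about 1000 transcripts per spot).
#'
#' @param image_shape integer (H, W).
#' @param regions list of regions; each
#'   \code{list(shape = "rectangle", geometry = c(x0, y0, x1, y1), color = c(r, g, b))}
#'   or \code{list(shape = "disk", geometry = c(cx, cy, radius), color = ...)},
#'   pixel coordinates 0-based, colours 0..255. Regions must not overlap.
#' @param spot_pitch lattice pitch in working pixels (>= 2).
#' @param n_genes,markers_per_region,marker_log2_fc,baseline_mean,dispersion
#'   expression model; \code{dispersion} is the NB dispersion (variance =
#'   mu + dispersion * mu^2), \code{marker_log2_fc > 0}.
#' @param n_cell_types number of deconvolution cell types.
#' @param n_decoy_terms decoy gene-set terms of random non-marker genes.
#' @param hires_scalef scale factor relating the stored full-resolution
#'   coordinates to the working image.
#' @param seed integer seed; the fixture is a pure function of these fields.
#' @return A \code{stroi_fixture_spec} list.
#' @export
fixture_spec <- function(image_shape = c(200L, 200L),
                         regions = default_regions(),
                         spot_pitch = 8,
                         n_genes = 2000,
                         markers_per_region = 10,
                         marker_log2_fc = 2,
                         baseline_mean = 0.5,
                         dispersion = 0.5,
                         n_cell_types = 5,
                         n_decoy_terms = 20,
                         hires_scalef = 0.5,
                         seed = 1) {
  if (spot_pitch < 2) stopf("spot_pitch must be >= 2")
  if (marker_log2_fc < 0) stopf("marker_log2_fc must be >= 0")
  structure(as.list(environment()), class = "stroi_fixture_spec")
}

default_regions <- function() {
  list(
    list(shape = "rectangle", geometry = c(20, 20, 90, 170),
         color = c(200L, 60L, 60L)),
    list(shape = "rectangle", geometry = c(110, 30, 180, 170),
         color = c(60L, 90L, 200L))
  )
}

region_raster <- function(region, shape) {
  H <- shape[1]; W <- shape[2]
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  if (region$shape == "rectangle") {
    g <- region$geometry
    xs >= g[1] & xs <= g[3] & ys >= g[2] & ys <= g[4]
  } else if (region$shape == "disk") {
    g <- region$geometry
    (xs - g[1])^2 + (ys - g[2])^2 <= g[3]^2
  } else stopf("unknown region shape '%s'", region$shape)
}

# Analytic point-in-region and point-near-region tests (margin in px).
point_in_region <- function(region, x, y, margin = 0) {
  if (region$shape == "rectangle") {
    g <- region$geometry
    x >= g[1] - margin & x <= g[3] + margin &
      y >= g[2] - margin & y <= g[4] + margin
  } else {
    g <- region$geometry
    (x - g[1])^2 + (y - g[2])^2 <= (g[3] + margin)^2
  }
}

#' Generate a synthetic spatial dataset with planted ground truth
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return List with \code{dataset} (a \code{stroi_dataset}; the image is
#'   the working image, i.e. the stored full-resolution coordinates times
#'   \code{hires_scalef} recover the lattice) and \code{ground_truth}:
#'   region rasters, per-spot region labels (0 = none), marker gene lists,
#'   the planted gene-set library (region terms + decoys), per-region
#'   cell-type profiles, and the per-spot fraction matrix.
#' @export
make_fixture <- function(spec = fixture_spec()) {
  H <- as.integer(spec$image_shape[1]); W <- as.integer(spec$image_shape[2])
  rasters <- lapply(spec$regions, region_raster, shape = c(H, W))
  if (length(rasters) > 1) {
    overlap <- Reduce(`+`, lapply(rasters, `+`, 0))
    if (any(overlap > 1)) stopf("fixture regions must not overlap")
  }

  image <- array(255L, dim = c(H, W, 3L))
  for (i in seq_along(rasters)) {
    col <- spec$regions[[i]]$color
    for (ch in 1:3) {
      plane <- image[, , ch]
      plane[rasters[[i]]] <- as.integer(col[ch])
      image[, , ch] <- plane
    }
  }

  # square lattice of spots over the working image
  gx <- seq(spec$spot_pitch / 2, W - 1, by = spec$spot_pitch)
  gy <- seq(spec$spot_pitch / 2, H - 1, by = spec$spot_pitch)
  sx <- rep(gx, times = length(gy))
  sy <- rep(gy, each = length(gx))

  region_of <- rep(0L, length(sx))
  near <- rep(FALSE, length(sx))
  for (i in seq_along(spec$regions)) {
    inside <- point_in_region(spec$regions[[i]], sx, sy)
    region_of[inside & region_of == 0L] <- i
    near <- near | point_in_region(spec$regions[[i]], sx, sy,
                                   margin = spec$spot_pitch)
  }
  in_tissue <- near

  n_spots <- length(sx)
  G <- spec$n_genes
  genes <- sprintf("G%04d", seq_len(G))
  markers <- list()
  for (i in seq_along(spec$regions))
    markers[[i]] <- genes[seq((i - 1) * spec$markers_per_region + 1,
                              i * spec$markers_per_region)]

  gt_lib <- make_fixture_library(spec, genes, markers)

  out <- with_local_seed(spec$seed, {
    mu <- matrix(spec$baseline_mean, nrow = n_spots, ncol = G)
    for (i in seq_along(markers)) {
      rows <- which(region_of == i)
      cols <- match(markers[[i]], genes)
      mu[rows, cols] <- mu[rows, cols] * 2^spec$marker_log2_fc
    }
    size <- 1 / spec$dispersion
    counts <- matrix(stats::rnbinom(n_spots * G, size = size,
                                    mu = as.vector(mu)),
                     nrow = n_spots, ncol = G)

    # per-region Dirichlet cell-type profiles; background profile is flat
    k <- spec$n_cell_types
    profiles <- matrix(NA_real_, nrow = length(spec$regions) + 1, ncol = k)
    rownames(profiles) <- c("background", paste0("region", seq_along(spec$regions)))
    profiles[1, ] <- rdirichlet1(rep(2, k))
    for (i in seq_along(spec$regions)) {
      alpha <- rep(1, k)
      alpha[(i - 1L) %% k + 1L] <- 8
      profiles[i + 1, ] <- rdirichlet1(alpha)
    }
    fractions <- t(vapply(seq_len(n_spots), function(s) {
      rdirichlet1(60 * profiles[region_of[s] + 1L, ])
    }, numeric(k)))
    colnames(fractions) <- paste0("CT", seq_len(k))
    list(counts = counts, fractions = fractions, profiles = profiles)
  })

  barcodes <- sprintf("SPOT-%04d", seq_len(n_spots))
  rownames(out$fractions) <- barcodes
  ds <- spatial_dataset(
    counts = methods::as(Matrix::Matrix(out$counts, sparse = TRUE),
                         "CsparseMatrix"),
    gene_ids = genes,
    spot_table = data.frame(
      barcode = barcodes,
      in_tissue = in_tissue,
      fullres_x = sx / spec$hires_scalef,
      fullres_y = sy / spec$hires_scalef,
      stringsAsFactors = FALSE
    ),
    scale = list(hires_scalef = spec$hires_scalef,
                 spot_diameter_fullres = 0.9 * spec$spot_pitch / spec$hires_scalef),
    image = image
  )

  list(
    dataset = ds,
    ground_truth = list(
      region_rasters = rasters,
      spot_region = region_of,
      markers = markers,
      library = gt_lib,
      profiles = out$profiles,
      fractions = out$fractions
    )
  )
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Planted library: one term of the true markers per region plus decoy
# terms of random non-marker genes (seeded independently of the counts).
make_fixture_library <- function(spec, genes, markers) {
  terms <- list()
  for (i in seq_along(markers))
    terms[[sprintf("REGION%d_MARKERS", i)]] <- markers[[i]]
  non_markers <- setdiff(genes, unlist(markers))
  decoys <- with_local_seed(spec$seed + 101L, {
    lapply(seq_len(spec$n_decoy_terms), function(i)
      sample(non_markers, spec$markers_per_region))
  })
  for (i in seq_along(decoys))
    terms[[sprintf("DECOY_%02d", i)]] <- decoys[[i]]
  gene_set_library(terms, name = "planted")
}

#' Write a fixture to disk as a Visium-style bundle
#'
#' Produces the on-disk layout \code{\link{read_visium_bundle}} consumes
#' (MTX triplet matrix, tissue positions CSV, scale-factors JSON, PNG
#' image) plus the planted gene-set library in GMT, the cell-type fraction
#' CSV, and a ground-truth JSON.
#'
#' @param fx a \code{\link{make_fixture}} result.
#' @param dir output directory (created).
#' @param positions_dialect \code{"header"} or \code{"headerless"}.
#' @return \code{dir}, invisibly.
#' @export
write_visium_fixture <- function(fx, dir,
                                 positions_dialect = c("header", "headerless")) {
  positions_dialect <- match.arg(positions_dialect)
  ds <- fx$dataset
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  m <- Matrix::t(ds$counts)   # genes x barcodes
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(id = ds$gene_ids, symbol = ds$gene_ids,
               type = "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(ds$spot_table$barcode, file.path(dir, "barcodes.tsv"))

  pos <- data.frame(
    barcode = ds$spot_table$barcode,
    in_tissue = as.integer(ds$spot_table$in_tissue),
    array_row = seq_len(nrow(ds$spot_table)) - 1L,
    array_col = seq_len(nrow(ds$spot_table)) - 1L,
    pxl_row_in_fullres = ds$spot_table$fullres_y,
    pxl_col_in_fullres = ds$spot_table$fullres_x
  )
  utils::write.table(pos, file.path(dir, "tissue_positions.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = (positions_dialect == "header"))

  jsonlite::write_json(
    list(tissue_hires_scalef = ds$scale$hires_scalef,
         spot_diameter_fullres = ds$scale$spot_diameter_fullres),
    file.path(dir, "scalefactors_json.json"), auto_unbox = TRUE, digits = NA)

  write_rgb_image(ds$image, file.path(dir, "tissue_hires_image.png"))
  write_gmt(fx$ground_truth$library, file.path(dir, "gene_sets.gmt"))

  fr <- data.frame(barcode = rownames(fx$ground_truth$fractions),
                   fx$ground_truth$fractions, check.names = FALSE)
  utils::write.csv(fr, file.path(dir, "fractions.csv"), row.names = FALSE,
                   quote = FALSE)

  jsonlite::write_json(
    list(spot_region = fx$ground_truth$spot_region,
         markers = fx$ground_truth$markers),
    file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}
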