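test_that("a written Visium bundle reads back losslessly", {
  fx <- make_fixture(small_fixture_spec())
  dir <- withr::local_tempdir()
  write_visium_fixture(fx, dir)

  ds <- read_visium_bundle(dir, file.path(dir, "tissue_positions.csv"),
                           file.path(dir, "scalefactors_json.json"),
                           file.path(dir, "tissue_hires_image.png"))

  expect_equal(as.matrix(ds$counts), as.matrix(fx$dataset$counts),
               ignore_attr = TRUE)
  expect_identical(ds$gene_ids, fx$dataset$gene_ids)
  expect_identical(ds$spot_table$barcode, fx$dataset$spot_table$barcode)
  expect_identical(ds$spot_table$in_tissue, fx$dataset$spot_table$in_tissue)
  # coordinates and scale factors are exact, not approximate
  expect_identical(ds$spot_table$fullres_x, fx$dataset$spot_table$fullres_x)
  expect_identical(ds$spot_table$fullres_y, fx$dataset$spot_table$fullres_y)
  expect_equal(ds$scale, fx$dataset$scale)
  expect_identical(ds$image, fx$dataset$image)
})

test_that("a tiny MTX fixture matches its written triplets exactly", {
  dir <- withr::local_tempdir()
  counts <- matrix(c(0, 5, 0, 2,
                     1, 0, 0, 0,
                     0, 3, 7, 0), nrow = 3, byrow = TRUE)
  Matrix::writeMM(Matrix::Matrix(t(counts), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  write.table(data.frame(paste0("ENSG", 1:4), c("TP53", "ACTB", "CD3E", "EPCAM"),
                         "Gene Expression"),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(c("AAA-1", "BBB-1", "CCC-1"), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(c("AAA-1", "BBB-1", "CCC-1"), 1, 0, 0,
                         c(10, 20, 30), c(40, 50, 60)),
              file.path(dir, "pos.csv"), sep = ",", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(tissue_hires_scalef = 0.5,
                            spot_diameter_fullres = 10),
                       file.path(dir, "sf.json"), auto_unbox = TRUE)
  png::writePNG(array(0.5, c(8, 8, 3)), file.path(dir, "img.png"))

  ds <- read_visium_bundle(dir, file.path(dir, "pos.csv"),
                           file.path(dir, "sf.json"),
                           file.path(dir, "img.png"))
  expect_equal(as.matrix(ds$counts), counts, ignore_attr = TRUE)
  expect_identical(ds$gene_ids, c("TP53", "ACTB", "CD3E", "EPCAM"))
  expect_identical(ds$spot_table$fullres_x, c(40, 50, 60))  # pxl_col = x
  expect_identical(ds$spot_table$fullres_y, c(10, 20, 30))  # pxl_row = y
})

test_that("header and headerless positions dialects give identical datasets", {
  fx <- make_fixture(small_fixture_spec())
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_visium_fixture(fx, d1, positions_dialect = "header")
  write_visium_fixture(fx, d2, positions_dialect = "headerless")
  read1 <- read_visium_bundle(d1, file.path(d1, "tissue_positions.csv"),
                              file.path(d1, "scalefactors_json.json"),
                              file.path(d1, "tissue_hires_image.png"))
  read2 <- read_visium_bundle(d2, file.path(d2, "tissue_positions.csv"),
                              file.path(d2, "scalefactors_json.json"),
                              file.path(d2, "tissue_hires_image.png"))
  expect_equal(read1, read2)
})

test_that("barcode mismatches between matrix and positions are hard errors", {
  fx <- make_fixture(small_fixture_spec())
  dir <- withr::local_tempdir()
  write_visium_fixture(fx, dir)
  pos_path <- file.path(dir, "tissue_positions.csv")
  pos <- read.csv(pos_path)
  args <- function(p) list(dir, p, file.path(dir, "scalefactors_json.json"),
                           file.path(dir, "tissue_hires_image.png"))

  # positions missing a matrix barcode
  drop_path <- file.path(dir, "pos_drop.csv")
  write.csv(pos[-1, ], drop_path, row.names = FALSE, quote = FALSE)
  expect_error(do.call(read_visium_bundle, args(drop_path)),
               "barcode mismatch.*SPOT-0001")

  # positions with a barcode the matrix does not have
  extra <- pos[1, ]; extra$barcode <- "GHOST-1"
  extra_path <- file.path(dir, "pos_extra.csv")
  write.csv(rbind(pos, extra), extra_path, row.names = FALSE, quote = FALSE)
  expect_error(do.call(read_visium_bundle, args(extra_path)), "GHOST-1")
  ds <- do.call(read_visium_bundle,
                c(args(extra_path), list(extra_positions = "drop")))
  expect_identical(ds$spot_table$barcode, fx$dataset$spot_table$barcode)
})

test_that("duplicate gene symbols are suffixed, and 10x HDF5 matches MTX", {
  fx <- make_fixture(small_fixture_spec())
  dir <- withr::local_tempdir()
  write_visium_fixture(fx, dir)
  # duplicate a symbol in features.tsv
  feat <- read.delim(file.path(dir, "features.tsv"), header = FALSE)
  feat[2, 2] <- feat[1, 2]
  write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  ds <- read_visium_bundle(dir, file.path(dir, "tissue_positions.csv"),
                           file.path(dir, "scalefactors_json.json"),
                           file.path(dir, "tissue_hires_image.png"))
  expect_identical(ds$gene_ids[1:2],
                   c(feat[1, 2], paste0(feat[1, 2], "_2")))

  # same content through the 10x HDF5 layout
  h5 <- file.path(dir, "filtered_feature_bc_matrix.h5")
  m <- Matrix::t(fx$dataset$counts)          # genes x barcodes CSC
  rhdf5::h5createFile(h5)
  rhdf5::h5createGroup(h5, "matrix")
  rhdf5::h5createGroup(h5, "matrix/features")
  rhdf5::h5write(m@x, h5, "matrix/data")
  rhdf5::h5write(m@i, h5, "matrix/indices")
  rhdf5::h5write(m@p, h5, "matrix/indptr")
  rhdf5::h5write(dim(m), h5, "matrix/shape")
  rhdf5::h5write(fx$dataset$spot_table$barcode, h5, "matrix/barcodes")
  rhdf5::h5write(fx$dataset$gene_ids, h5, "matrix/features/name")
  ds_h5 <- read_visium_bundle(h5, file.path(dir, "tissue_positions.csv"),
                              file.path(dir, "scalefactors_json.json"),
                              file.path(dir, "tissue_hires_image.png"))
  expect_equal(as.matrix(ds_h5$counts), as.matrix(fx$dataset$counts),
               ignore_attr = TRUE)
})

test_that("GMT parsing handles short lines, empty sets and duplicate names", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "TERM_A\tdesc\tG1\tG2",
    "SHORT",
    "TERM_B\tdesc\tg3\tG4\tG5",
    "EMPTY\tdesc\t\t",
    "TERM_A\tdesc\tG9"
  ), path)
  expect_warning(expect_warning(lib <- read_gmt(path), "fewer than 3"),
                 "empty gene lists")
  expect_named(lib$terms, c("TERM_A", "TERM_B", "TERM_A_2"))
  expect_identical(lib$terms$TERM_A, c("G1", "G2"))
  expect_identical(lib$terms$TERM_B, c("G3", "G4", "G5"))  # uppercased

  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(0), empty)
  expect_error(read_gmt(empty), "empty")
})

test_that("GMT round-trips through write_gmt", {
  set.seed(11)
  terms <- lapply(1:5, function(i) sprintf("GENE%02d", sample(50, i + 2)))
  names(terms) <- sprintf("SET_%d", 1:5)
  lib <- gene_set_library(terms, name = "rt")
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(lib, path)
  back <- read_gmt(path, name = "rt")
  expect_equal(back$terms, lib$terms)
  expect_identical(lengths(back$terms), lengths(lib$terms))
})

test_that("mask sets validate ordering and shape invariants", {
  shape <- c(30L, 40L)
  set.seed(5)
  masks <- lapply(1:6, function(i) {
    r <- matrix(runif(prod(shape)) < runif(1, 0.05, 0.5), shape[1], shape[2])
    if (!any(r)) r[1, 1] <- TRUE
    segment_mask(r)
  })
  ms <- postprocess_masks(masks, shape, mode = "everything")
  areas <- vapply(ms$masks, `[[`, 0L, "area_px")
  expect_true(all(diff(areas) <= 0))
  expect_identical(vapply(ms$masks, `[[`, 0L, "mask_id"), seq_along(masks))
  expect_error(postprocess_masks(masks, c(31L, 40L), mode = "everything"),
               "shape")
  expect_error(segment_mask(matrix(FALSE, 2, 2)), "no TRUE pixels")
  expect_error(segment_mask(matrix(TRUE, 2, 2), score = 1.2), "\\[0, 1\\]")
})
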