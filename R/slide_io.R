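#' @importFrom methods as new
#' @importFrom stats median quantile rnorm runif rpois rnbinom cor sd setNames
#' @importFrom utils head write.csv read.csv
NULL

# ---- domain type constructors -----------------------------------------------

#' Scale-factor metadata for a slide
#'
#' Holds the two pieces of scaling metadata the pipeline needs: the imaging
#' resolution in microns per pixel and the assay spot diameter in full-
#' resolution pixels (used as crop padding).
#'
#' @param microns_per_pixel Imaging resolution, um/px. Must be > 0.
#' @param spot_diameter_fullres Spot diameter in full-resolution pixels. Must
#'   be > 0.
#' @return An object of class `scale_factors`.
#' @export
scale_factors <- function(microns_per_pixel, spot_diameter_fullres) {
  stopifnot(is.numeric(microns_per_pixel), length(microns_per_pixel) == 1L,
            is.numeric(spot_diameter_fullres), length(spot_diameter_fullres) == 1L)
  if (!is.finite(microns_per_pixel) || microns_per_pixel <= 0)
    stop("microns_per_pixel must be strictly positive")
  if (!is.finite(spot_diameter_fullres) || spot_diameter_fullres <= 0)
    stop("spot_diameter_fullres must be strictly positive")
  structure(list(microns_per_pixel = microns_per_pixel,
                 spot_diameter_fullres = spot_diameter_fullres),
            class = "scale_factors")
}

#' Spot position table
#'
#' A data frame of assay spot positions in the full-resolution pixel frame.
#' Coordinates are 0-based; `in_tissue` flags spots under tissue.
#'
#' @param spot_id Character vector of unique spot identifiers (barcodes).
#' @param pxl_row_in_fullres,pxl_col_in_fullres Non-negative integer pixel
#'   coordinates in the full-resolution frame (0-based).
#' @param in_tissue Logical (or 0/1) tissue flag.
#' @return A `data.frame` with class `spot_table`.
#' @export
spot_table <- function(spot_id, pxl_row_in_fullres, pxl_col_in_fullres, in_tissue) {
  spot_id <- as.character(spot_id)
  if (anyDuplicated(spot_id)) stop("spot_id values must be unique")
  r <- as.integer(pxl_row_in_fullres); c <- as.integer(pxl_col_in_fullres)
  if (any(r < 0) || any(c < 0)) stop("spot pixel coordinates must be non-negative")
  df <- data.frame(spot_id = spot_id,
                   pxl_row_in_fullres = r,
                   pxl_col_in_fullres = c,
                   in_tissue = as.logical(in_tissue),
                   stringsAsFactors = FALSE)
  class(df) <- c("spot_table", "data.frame")
  df
}

#' Nuclei table
#'
#' Couples per-nucleus centroids (pixel coordinates in the cropped frame),
#' detection probabilities and an embedding matrix, plus an optional label
#' vector that annotation steps fill in.
#'
#' @param centroid_row,centroid_col Integer centroid coordinates (px, cropped
#'   frame, 0-based).
#' @param embedding Numeric matrix, one row per nucleus (N x D).
#' @param detection_prob Numeric in \[0, 1\].
#' @param label Optional character vector of labels (NA where unset).
#' @param nucleus_id Optional integer ids; defaults to `seq_len(N) - 1L`.
#' @return An object of class `nuclei_table` with elements `info`
#'   (data.frame) and `embedding` (matrix).
#' @export
nuclei_table <- function(centroid_row, centroid_col, embedding,
                         detection_prob = NULL, label = NULL, nucleus_id = NULL) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (length(centroid_row) != n || length(centroid_col) != n)
    stop("centroid vectors must match embedding row count")
  if (any(!is.finite(embedding))) stop("nucleus embeddings contain non-finite values")
  if (is.null(detection_prob)) detection_prob <- rep(1, n)
  if (any(detection_prob < 0 | detection_prob > 1))
    stop("detection_prob must lie in [0, 1]")
  if (is.null(label)) label <- rep(NA_character_, n)
  if (is.null(nucleus_id)) nucleus_id <- seq_len(n) - 1L
  info <- data.frame(nucleus_id = as.integer(nucleus_id),
                     centroid_row = as.integer(centroid_row),
                     centroid_col = as.integer(centroid_col),
                     detection_prob = as.numeric(detection_prob),
                     label = as.character(label),
                     stringsAsFactors = FALSE)
  structure(list(info = info, embedding = embedding), class = "nuclei_table")
}

#' @export
print.nuclei_table <- function(x, ...) {
  cat(sprintf("<nuclei_table> %d nuclei, %d-dim embeddings, %d labeled\n",
              nrow(x$info), ncol(x$embedding), sum(!is.na(x$info$label))))
  invisible(x)
}

#' Number of nuclei in a table
#' @param x A `nuclei_table`.
#' @return Integer count.
#' @export
n_nuclei <- function(x) nrow(x$info)

# ---- crop bounds ------------------------------------------------------------

#' Compute the tissue crop bounds from spot positions
#'
#' The crop is the minimum bounding rectangle over all in-tissue spots,
#' expanded on every side by the spot diameter so spot boundaries are fully
#' captured, then clamped at 0. Intervals are half-open `[min, max)` in the
#' full-resolution frame.
#'
#' @param spots A [spot_table()].
#' @param sf A [scale_factors()].
#' @return A list with class `crop_bounds`: `row_min`, `row_max`, `col_min`,
#'   `col_max` (integers, half-open).
#' @export
compute_crop_bounds <- function(spots, sf) {
  stopifnot(inherits(spots, "spot_table"), inherits(sf, "scale_factors"))
  tissue <- spots[spots$in_tissue, , drop = FALSE]
  if (nrow(tissue) == 0L) stop("no in-tissue spots: cannot compute crop bounds")
  d <- sf$spot_diameter_fullres
  bounds <- list(
    row_min = as.integer(max(0, floor(min(tissue$pxl_row_in_fullres) - d))),
    row_max = as.integer(ceiling(max(tissue$pxl_row_in_fullres) + d) + 1L),
    col_min = as.integer(max(0, floor(min(tissue$pxl_col_in_fullres) - d))),
    col_max = as.integer(ceiling(max(tissue$pxl_col_in_fullres) + d) + 1L))
  class(bounds) <- "crop_bounds"
  bounds
}

# ---- readers / writers ------------------------------------------------------

#' Read scale-factor metadata from a scalefactors JSON file
#'
#' @param path Path to a `scalefactors_json.json`-style file.
#' @return A [scale_factors()] object.
#' @export
read_scalefactors <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("microns_per_pixel", "spot_diameter_fullres"))
    if (is.null(j[[k]])) stop("scalefactors file missing required field: ", k)
  scale_factors(j$microns_per_pixel, j$spot_diameter_fullres)
}

#' Write scale-factor metadata as JSON
#' @param sf A [scale_factors()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scalefactors <- function(sf, path) {
  stopifnot(inherits(sf, "scale_factors"))
  jsonlite::write_json(unclass(sf), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read spot positions from a tissue-positions Parquet (or CSV) file
#'
#' Requires columns `barcode` (or `spot_id`), `in_tissue`,
#' `pxl_row_in_fullres`, `pxl_col_in_fullres`.
#'
#' @param path Path to `tissue_positions.parquet` (or a `.csv` with the same
#'   columns).
#' @return A [spot_table()].
#' @export
read_spot_positions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (grepl("\\.csv$", path)) read.csv(path, stringsAsFactors = FALSE)
        else as.data.frame(arrow::read_parquet(path))
  id_col <- if ("barcode" %in% names(df)) "barcode" else "spot_id"
  for (k in c(id_col, "in_tissue", "pxl_row_in_fullres", "pxl_col_in_fullres"))
    if (!k %in% names(df)) stop("positions file missing required column: ", k)
  spot_table(df[[id_col]], df$pxl_row_in_fullres, df$pxl_col_in_fullres,
             df$in_tissue)
}

#' Write spot positions as Parquet
#' @param spots A [spot_table()].
#' @param path Output path (`.parquet`, or `.csv` for plain text).
#' @return `path`, invisibly.
#' @export
write_spot_positions <- function(spots, path) {
  stopifnot(inherits(spots, "spot_table"))
  df <- as.data.frame(spots)
  names(df)[names(df) == "spot_id"] <- "barcode"
  df$in_tissue <- as.integer(df$in_tissue)
  if (grepl("\\.csv$", path)) write.csv(df, path, row.names = FALSE)
  else arrow::write_parquet(df, path)
  invisible(path)
}

#' Read a spot-level count matrix
#'
#' Accepts either a 10x-style HDF5 file (group `matrix` with CSC `data` /
#' `indices` / `indptr` / `shape` and `features/name` gene symbols) or a
#' directory holding an MTX triplet (`matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`).
#'
#' @param path Path to the `.h5` file or MTX directory.
#' @return A genes x spots `dgCMatrix` with unique upper-cased-matchable gene
#'   symbols as rownames and spot ids as colnames.
#' @export
read_counts <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    bc <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, feat, bc)) if (!file.exists(f)) stop("counts bundle missing file: ", basename(f))
    m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    genes <- read.delim(feat, header = FALSE, stringsAsFactors = FALSE)[[1]]
    barcodes <- read.delim(bc, header = FALSE, stringsAsFactors = FALSE)[[1]]
  } else if (file.exists(path)) {
    h <- rhdf5::h5ls(path)
    if (!"matrix" %in% h$name[h$group == "/"]) stop("counts HDF5 missing required group: matrix")
    shape <- as.integer(rhdf5::h5read(path, "matrix/shape"))
    m <- Matrix::sparseMatrix(
      i = as.integer(rhdf5::h5read(path, "matrix/indices")) + 1L,
      p = as.integer(rhdf5::h5read(path, "matrix/indptr")),
      x = as.numeric(rhdf5::h5read(path, "matrix/data")),
      dims = shape)
    genes <- as.character(rhdf5::h5read(path, "matrix/features/name"))
    barcodes <- as.character(rhdf5::h5read(path, "matrix/barcodes"))
  } else stop("file not found: ", path)
  if (ncol(m) == 0L) stop("counts file contains 0 spots")
  if (length(genes) != nrow(m)) stop("dimension mismatch between features and matrix rows")
  if (length(barcodes) != ncol(m)) stop("dimension mismatch between barcodes and matrix columns")
  if (any(m@x < 0)) stop("counts must be non-negative")
  if (anyDuplicated(toupper(genes))) stop("gene symbols must be unique after upper-casing")
  dimnames(m) <- list(genes, barcodes)
  m
}

#' Write a count matrix as an MTX triplet directory
#' @param counts Genes x spots sparse matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene and spot dimnames")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write a count matrix in the 10x-style HDF5 layout
#' @param counts Genes x spots sparse matrix with dimnames.
#' @param path Output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_counts_h5 <- function(counts, path) {
  if (is.null(rownames(counts)) || (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must carry gene and spot dimnames")
  m <- methods::as(counts, "CsparseMatrix")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "matrix")
  rhdf5::h5createGroup(path, "matrix/features")
  rhdf5::h5write(m@x, path, "matrix/data")
  rhdf5::h5write(m@i, path, "matrix/indices")
  rhdf5::h5write(m@p, path, "matrix/indptr")
  rhdf5::h5write(dim(m), path, "matrix/shape")
  rhdf5::h5write(rownames(m), path, "matrix/features/name")
  rhdf5::h5write(if (is.null(colnames(m))) character(0) else colnames(m),
                 path, "matrix/barcodes")
  rhdf5::h5closeAll()
  invisible(path)
}

# Nuclei HDF5 layout: group SegmentationNode with parallel datasets
#   embedding      (D x N in file; transposed on read/write)
#   nucleus_id, centroid_row, centroid_col, detection_prob, label
NUCLEI_GROUP <- "SegmentationNode"

#' Write a nuclei table to HDF5
#'
#' Layout: group `SegmentationNode` holding `embedding` plus parallel
#' datasets `nucleus_id`, `centroid_row`, `centroid_col`, `detection_prob`
#' and `label` (empty string where unset).
#'
#' @param nuclei A [nuclei_table()].
#' @param path Output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_nuclei <- function(nuclei, path) {
  stopifnot(inherits(nuclei, "nuclei_table"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, NUCLEI_GROUP)
  g <- function(d) paste0(NUCLEI_GROUP, "/", d)
  rhdf5::h5write(t(nuclei$embedding), path, g("embedding"))
  rhdf5::h5write(nuclei$info$nucleus_id, path, g("nucleus_id"))
  rhdf5::h5write(nuclei$info$centroid_row, path, g("centroid_row"))
  rhdf5::h5write(nuclei$info$centroid_col, path, g("centroid_col"))
  rhdf5::h5write(nuclei$info$detection_prob, path, g("detection_prob"))
  lab <- nuclei$info$label
  lab[is.na(lab)] <- ""
  rhdf5::h5write(lab, path, g("label"))
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a nuclei table from HDF5
#' @param path Path to a nuclei HDF5 file written by [write_nuclei()] (group
#'   `SegmentationNode`).
#' @return A [nuclei_table()].
#' @export
read_nuclei <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  h <- rhdf5::h5ls(path)
  if (!NUCLEI_GROUP %in% h$name[h$group == "/"])
    stop("nuclei HDF5 missing required group: ", NUCLEI_GROUP)
  present <- h$name[h$group == paste0("/", NUCLEI_GROUP)]
  for (d in c("embedding", "centroid_row", "centroid_col"))
    if (!d %in% present) stop("nuclei HDF5 missing required dataset: ", d)
  g <- function(d) paste0(NUCLEI_GROUP, "/", d)
  emb <- t(rhdf5::h5read(path, g("embedding")))
  lab <- if ("label" %in% present) as.character(rhdf5::h5read(path, g("label"))) else NULL
  if (!is.null(lab)) lab[lab == ""] <- NA_character_
  nuclei_table(
    centroid_row = as.integer(rhdf5::h5read(path, g("centroid_row"))),
    centroid_col = as.integer(rhdf5::h5read(path, g("centroid_col"))),
    embedding = emb,
    detection_prob = if ("detection_prob" %in% present)
      as.numeric(rhdf5::h5read(path, g("detection_prob"))) else NULL,
    label = lab,
    nucleus_id = if ("nucleus_id" %in% present)
      as.integer(rhdf5::h5read(path, g("nucleus_id"))) else NULL)
}

# ---- ROI report -------------------------------------------------------------

#' Write an ROI ranking report
#'
#' Writes the ranking as CSV (`rank`, `anchor_row`, `anchor_col`, `score`
#' plus any component-score columns) and a JSON run manifest alongside it
#' (same path with `_manifest.json`).
#'
#' @param ranking A [region_ranking()] (non-empty).
#' @param path Output CSV path.
#' @param config Optional named list recorded in the manifest.
#' @param seed Optional seed recorded in the manifest.
#' @return `path`, invisibly.
#' @export
write_roi_report <- function(ranking, path, config = list(), seed = NULL) {
  stopifnot(inherits(ranking, "region_ranking"))
  if (nrow(ranking) == 0L) stop("cannot write a report for an empty ranking")
  df <- as.data.frame(ranking)
  df <- cbind(rank = seq_len(nrow(df)), df)
  write.csv(df, path, row.names = FALSE)
  manifest <- list(
    method = attr(ranking, "method"),
    n_windows = nrow(df),
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("roirank")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, sub("\\.csv$", "_manifest.json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an ROI ranking report written by [write_roi_report()]
#' @param path CSV path.
#' @return A [region_ranking()].
#' @export
read_roi_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  manifest_path <- sub("\\.csv$", "_manifest.json", path)
  method <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path)$method else "unknown"
  df$rank <- NULL
  region_ranking(df, method = method)
}
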