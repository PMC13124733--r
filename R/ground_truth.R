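# Expression-derived ground truth: classify spots by marker-gene
# expression, then aggregate spot classifications into regional rankings
# over the same sliding-window lattice used by the model.

#' Packaged marker gene sets
#'
#' Canonical marker sets per tissue context, stored as editable JSON under
#' `inst/extdata/markers/`. Each is a named list mapping a cell-type name to
#' its marker gene symbols; the first type named `tumor` (when present)
#' serves as the default target for tumor-count ground truth.
#'
#' @param name `"lung_colon"`, `"prostate"` or `"kidney"`, or a path to a
#'   JSON file with the same structure.
#' @return A named list of class `marker_set`.
#' @export
load_marker_set <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "markers", paste0(name, ".json"), package = "roirank")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown marker set: ", name)
  ms <- jsonlite::read_json(path, simplifyVector = TRUE)
  marker_set(ms)
}

#' Construct a marker set
#' @param sets Named list: cell-type name -> character vector of gene
#'   symbols (non-empty).
#' @return A named list of class `marker_set`.
#' @export
marker_set <- function(sets) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("marker set types must be uniquely named")
  if (any(vapply(sets, length, 1L) == 0)) stop("marker gene lists must be non-empty")
  structure(lapply(sets, as.character), class = "marker_set")
}

#' CP10K log normalization of a count matrix
#'
#' Per spot, counts are scaled to 10,000 total and transformed with
#' `log(1 + x)` (natural log). Spots with zero total counts are dropped
#' with a warning.
#'
#' @param counts Genes x spots sparse (or dense) non-negative matrix.
#' @return Genes x spots `dgCMatrix` of normalized values.
#' @export
normalize_counts <- function(counts) {
  if (length(counts) == 0 || ncol(counts) == 0) stop("empty count matrix")
  m <- methods::as(counts, "CsparseMatrix")
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " spot(s) with zero total counts dropped")
    m <- m[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  if (ncol(m) == 0) stop("no spots with positive total counts")
  scaled <- m %*% Matrix::Diagonal(x = 1e4 / totals)
  scaled@x <- log1p(scaled@x)
  colnames(scaled) <- colnames(m)
  rownames(scaled) <- rownames(m)
  methods::as(scaled, "CsparseMatrix")
}

#' Classify spots by mean marker expression
#'
#' For each spot and cell type, the score is the mean normalized expression
#' over the type's marker genes present in the matrix (matched
#' case-insensitively; missing genes are dropped per type with a warning, a
#' type with no present marker is an error). A spot is assigned the argmax
#' type if its score reaches `threshold` (default 1.0 normalized expression
#' units), otherwise `"Unclassified"`. Exact ties break to the first type
#' in marker-set order.
#'
#' @param normed Genes x spots normalized matrix ([normalize_counts()]).
#' @param markers A [marker_set()].
#' @param threshold Minimum winning score (default 1.0).
#' @return Data frame: `spot_id`, one score column per type, `type`.
#' @export
classify_spots <- function(normed, markers, threshold = 1.0) {
  stopifnot(inherits(markers, "marker_set"))
  genes_upper <- toupper(rownames(normed))
  scores <- vapply(names(markers), function(ty) {
    hit <- match(toupper(markers[[ty]]), genes_upper)
    if (all(is.na(hit)))
      stop("no marker gene of type '", ty, "' found in the gene universe")
    if (anyNA(hit))
      warning("type '", ty, "': ", sum(is.na(hit)), " marker gene(s) absent, dropped")
    hit <- hit[!is.na(hit)]
    Matrix::colMeans(normed[hit, , drop = FALSE])
  }, numeric(ncol(normed)))
  scores <- matrix(scores, nrow = ncol(normed),
                   dimnames = list(colnames(normed), names(markers)))
  best <- argmax_first(scores)
  best_score <- scores[cbind(seq_len(nrow(scores)), best)]
  type <- ifelse(best_score >= threshold, names(markers)[best], "Unclassified")
  out <- data.frame(spot_id = colnames(normed), stringsAsFactors = FALSE)
  for (ty in names(markers)) out[[paste0("score_", ty)]] <- scores[, ty]
  out$type <- type
  out
}

#' Assign spots to patches of the cropped lattice
#'
#' `patch_row = floor((pxl_row - crop$row_min) / patch_px)`, likewise for
#' columns; spots outside the crop are dropped.
#'
#' @param spots A [spot_table()] (full-resolution frame).
#' @param crop A [compute_crop_bounds()] result.
#' @param patch_px Patch side in pixels (default 224).
#' @return `spots` with added `patch_row`, `patch_col`, restricted to spots
#'   inside the crop.
#' @export
assign_spots_to_patches <- function(spots, crop, patch_px = 224L) {
  inside <- spots$pxl_row_in_fullres >= crop$row_min &
            spots$pxl_row_in_fullres <  crop$row_max &
            spots$pxl_col_in_fullres >= crop$col_min &
            spots$pxl_col_in_fullres <  crop$col_max
  out <- as.data.frame(spots)[inside, , drop = FALSE]
  out$patch_row <- (out$pxl_row_in_fullres - crop$row_min) %/% patch_px
  out$patch_col <- (out$pxl_col_in_fullres - crop$col_min) %/% patch_px
  rownames(out) <- NULL
  out
}

#' Ground-truth diversity ranking from classified spots
#'
#' Per window: Shannon entropy (base 2) of the classified-spot type
#' proportions times `log(1 + N_spots)`; zero below `min_spots` spots.
#' Unclassified spots are excluded from both the proportions and `N` unless
#' `include_unclassified` is set.
#'
#' @param classified Data frame from [classify_spots()] joined with patch
#'   coordinates (`patch_row`, `patch_col`, `type`).
#' @param grid A [build_grid()] lattice.
#' @param cfg A [score_config()] (window, stride, `min_cells` reused as the
#'   minimum spot count).
#' @param include_unclassified Keep `"Unclassified"` as a category?
#' @return A [region_ranking()] (method `"gt_diversity"`).
#' @export
gt_diversity_ranking <- function(classified, grid, cfg = score_config(),
                                 include_unclassified = FALSE) {
  windows <- sliding_windows(grid, cfg)
  type <- classified$type
  if (!include_unclassified) type[type == "Unclassified"] <- NA
  classes <- sort(unique(type[!is.na(type)]))
  score <- if (length(classes) == 0) rep(0, nrow(windows)) else {
    counts <- window_class_counts(grid, windows, classified$patch_row,
                                  classified$patch_col, type, classes,
                                  cfg$window)
    window_entropy_scores(counts, cfg$min_cells)
  }
  region_ranking(data.frame(anchor_row = windows$anchor_row,
                            anchor_col = windows$anchor_col, score = score),
                 method = "gt_diversity")
}

#' Ground-truth tumor ranking from classified spots
#'
#' Per window: the count of spots classified as the tumor type, ranked in
#' descending order.
#'
#' @param classified As in [gt_diversity_ranking()].
#' @param grid A [build_grid()] lattice.
#' @param cfg A [score_config()].
#' @param tumor_class Name of the tumor type (default `"tumor"`).
#' @return A [region_ranking()] (method `"gt_tumor"`).
#' @export
gt_tumor_ranking <- function(classified, grid, cfg = score_config(),
                             tumor_class = "tumor") {
  if (!tumor_class %in% classified$type)
    stop("no spots classified as '", tumor_class, "'")
  windows <- sliding_windows(grid, cfg)
  counts <- window_class_counts(grid, windows, classified$patch_row,
                                classified$patch_col, classified$type,
                                tumor_class, cfg$window)
  region_ranking(data.frame(anchor_row = windows$anchor_row,
                            anchor_col = windows$anchor_col,
                            score = counts[, 1]),
                 method = "gt_tumor")
}

#' Sum native-resolution pixels into binned spots
#'
#' Optional helper for count matrices delivered at the assay's native pixel
#' resolution: sums counts over `bin x bin` blocks of the pixel lattice.
#'
#' @param counts Genes x pixels sparse matrix.
#' @param px_row,px_col Integer pixel lattice coordinates per column of
#'   `counts`.
#' @param bin Block side in native pixels (default 4, e.g. 2 um -> 8 um).
#' @return List: `counts` (genes x bins), `bin_row`, `bin_col`.
#' @export
bin_spots <- function(counts, px_row, px_col, bin = 4L) {
  br <- px_row %/% bin; bc <- px_col %/% bin
  key <- paste(br, bc, sep = "_")
  groups <- factor(key, levels = unique(key))
  agg <- counts %*% Matrix::sparseMatrix(
    i = seq_along(groups), j = as.integer(groups), x = 1,
    dims = c(length(groups), nlevels(groups)))
  first <- !duplicated(key)
  colnames(agg) <- unique(key)
  list(counts = methods::as(agg, "CsparseMatrix"),
       bin_row = br[first], bin_col = bc[first])
}
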