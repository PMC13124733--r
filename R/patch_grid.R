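# Patch lattice and background filtering.
#
# The cropped slide is divided into a non-overlapping 224 x 224 px lattice;
# incomplete edge tiles are conceptually padded with white. Filtering is a
# three-step cascade: a prefilter (all-white / all-black) applied before
# embedding, then two post-embedding tiers driven by grayscale statistics.

#' Default filter thresholds
#'
#' Tier 1 flags strong background: mean grayscale >= `tier1_mean` and
#' population standard deviation < `tier1_std`; when the color check is
#' enabled it additionally requires that at least `bright_frac` of pixels
#' have all RGB channels >= `bright_level`. Tier 2 flags remaining
#' low-variance patches with std < `tier2_std`.
#'
#' @param tier1_mean,tier1_std,tier2_std,bright_level,bright_frac Numeric
#'   thresholds.
#' @param color_check Logical; whether tier 1 runs the bright-RGB check.
#' @return A named list of thresholds.
#' @export
filter_config <- function(tier1_mean = 235, tier1_std = 20, tier2_std = 10,
                          bright_level = 230, bright_frac = 0.85,
                          color_check = FALSE) {
  list(tier1_mean = tier1_mean, tier1_std = tier1_std, tier2_std = tier2_std,
       bright_level = bright_level, bright_frac = bright_frac,
       color_check = isTRUE(color_check))
}

#' Build a patch lattice over a cropped image
#'
#' Patch `(r, c)` (0-based) covers pixels `[224r, 224r + 224) x
#' [224c, 224c + 224)`; edge patches extending past the image are padded
#' with white pixels, which participate in patch statistics.
#'
#' @param image_height_px,image_width_px Cropped image dimensions in pixels.
#' @param patch_px Patch side length in pixels (default 224).
#' @return An object of class `patch_grid` with `n_rows`, `n_cols`,
#'   `patch_px` and a per-patch data frame `patches` (row-major order) whose
#'   flag and stat columns start `NA` until [apply_filters()] runs.
#' @export
build_grid <- function(image_height_px, image_width_px, patch_px = 224L) {
  if (image_height_px < 1 || image_width_px < 1)
    stop("image dimensions must be positive")
  n_rows <- as.integer(ceiling(image_height_px / patch_px))
  n_cols <- as.integer(ceiling(image_width_px / patch_px))
  patches <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  patches <- data.frame(row = patches$row, col = patches$col)
  patches$mean_gray <- NA_real_
  patches$std_gray <- NA_real_
  patches$frac_bright_rgb <- NA_real_
  patches$prefiltered_out <- NA
  patches$tier1_background <- NA
  patches$tier2_lowvar <- NA
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 patch_px = as.integer(patch_px), patches = patches),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  n_ret <- if (all(is.na(x$patches$prefiltered_out))) NA_integer_
           else sum(retained_patches(x))
  cat(sprintf("<patch_grid> %d x %d patches (%d px), retained: %s\n",
              x$n_rows, x$n_cols, x$patch_px,
              ifelse(is.na(n_ret), "unfiltered", n_ret)))
  invisible(x)
}

# Row-major linear index (1-based) of patch (row, col), both 0-based.
patch_index <- function(grid, row, col) row * grid$n_cols + col + 1L

#' Grayscale conversion of an RGB patch
#'
#' ITU-R 601 luma: `round(0.299 R + 0.587 G + 0.114 B)`.
#'
#' @param img `H x W x 3` numeric array with values in \[0, 255\].
#' @return `H x W` integer-valued matrix.
#' @export
patch_gray <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  round(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
}

#' Pixel statistics of a patch
#'
#' @param img `H x W x 3` array, values in \[0, 255\].
#' @param bright_level RGB level for the bright-pixel fraction (default 230).
#' @return List: `mean_gray`, `std_gray` (population sd of the grayscale
#'   patch), `frac_bright_rgb` (fraction of pixels with all channels >=
#'   `bright_level`).
#' @export
patch_stats <- function(img, bright_level = 230) {
  g <- patch_gray(img)
  n <- length(g)
  mu <- mean(g)
  list(mean_gray = mu,
       std_gray = sqrt(sum((g - mu)^2) / n),
       frac_bright_rgb = mean(pmin(img[, , 1], img[, , 2], img[, , 3]) >= bright_level))
}

#' Prefilter: completely white or completely black patches
#'
#' Flags a patch iff every pixel value equals 255 or every pixel value
#' equals 0 (strict equality). Runs before embedding.
#'
#' @param img `H x W x 3` array.
#' @return Logical flag.
#' @export
prefilter_patch <- function(img) {
  all(img == 255) || all(img == 0)
}

#' Tier-1 background filter
#'
#' Flags strong background: mean grayscale >= 235 and population std < 20;
#' with the color check enabled, additionally at least 85% of pixels must
#' have all RGB channels >= 230.
#'
#' @param img `H x W x 3` array (or `NULL` if `stats` given).
#' @param cfg A [filter_config()].
#' @param stats Optional precomputed [patch_stats()] list.
#' @return Logical flag.
#' @export
tier1_background <- function(img = NULL, cfg = filter_config(), stats = NULL) {
  if (is.null(stats)) stats <- patch_stats(img, cfg$bright_level)
  hit <- stats$mean_gray >= cfg$tier1_mean && stats$std_gray < cfg$tier1_std
  if (hit && cfg$color_check) hit <- stats$frac_bright_rgb >= cfg$bright_frac
  hit
}

#' Tier-2 low-variance filter
#'
#' Flags remaining low-variance patches: population std of the grayscale
#' patch < 10. Applied only to patches that survived the prefilter and
#' tier 1.
#'
#' @inheritParams tier1_background
#' @return Logical flag.
#' @export
tier2_lowvar <- function(img = NULL, cfg = filter_config(), stats = NULL) {
  if (is.null(stats)) stats <- patch_stats(img, cfg$bright_level)
  stats$std_gray < cfg$tier2_std
}

#' Apply the filter cascade to a grid from per-patch statistics
#'
#' Order is prefilter, then tier 1, then tier 2, each short-circuiting: a
#' prefiltered patch is never tier-flagged and a tier-1 patch is never
#' tier-2-flagged.
#'
#' @param grid A [build_grid()] lattice.
#' @param stats Data frame with one row per patch in row-major order:
#'   `mean_gray`, `std_gray`, `frac_bright_rgb`, and logical `all_white`,
#'   `all_black` for the prefilter.
#' @param cfg A [filter_config()].
#' @return The grid with flags and stats filled in.
#' @export
apply_filters <- function(grid, stats, cfg = filter_config()) {
  stopifnot(inherits(grid, "patch_grid"), nrow(stats) == nrow(grid$patches))
  p <- grid$patches
  p$mean_gray <- stats$mean_gray
  p$std_gray <- stats$std_gray
  p$frac_bright_rgb <- stats$frac_bright_rgb
  pre <- stats$all_white | stats$all_black
  t1 <- !pre & stats$mean_gray >= cfg$tier1_mean & stats$std_gray < cfg$tier1_std
  if (cfg$color_check) t1 <- t1 & stats$frac_bright_rgb >= cfg$bright_frac
  t2 <- !pre & !t1 & stats$std_gray < cfg$tier2_std
  p$prefiltered_out <- pre
  p$tier1_background <- t1
  p$tier2_lowvar <- t2
  grid$patches <- p
  grid
}

#' Logical vector of retained patches (row-major order)
#'
#' A patch is retained iff no filter flag is set.
#'
#' @param grid A filtered `patch_grid`.
#' @return Logical vector of length `n_rows * n_cols`.
#' @export
retained_patches <- function(grid) {
  p <- grid$patches
  if (all(is.na(p$prefiltered_out))) stop("grid has not been filtered yet")
  !(p$prefiltered_out | p$tier1_background | p$tier2_lowvar)
}
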