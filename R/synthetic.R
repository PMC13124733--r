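# Synthetic slide generator.
#
# Produces a fully self-contained slide: a patch lattice with exact pixel
# statistics, patch and nucleus embeddings from the synthetic backend,
# nuclei with hidden true cell types, a spot table with a negative-binomial
# count matrix whose marker genes are up-shifted in matching-type spots,
# and planted ground-truth rankings computed from the true labels.
#
# Patch images follow an exact block model: each 224-px patch is an 8x8
# lattice of constant 28-px blocks, so patch-level pixel statistics equal
# the statistics of the 64 block values. Full pixel arrays are realized on
# demand by realize_patch().

BLOCKS_PER_SIDE <- 8L

# palettes: rows are RGB block colors
.palette_background <- function() {
  g <- c(244, 246, 248, 250, 252)
  cbind(g, g, g)
}
.palette_tissue <- function(shift = 0) {
  # H&E-like mix of dark nuclei, eosin pink and pale lumen tones
  base <- rbind(c(90, 60, 130), c(150, 90, 160), c(220, 160, 200),
                c(235, 200, 225), c(245, 240, 245))
  pmin(pmax(base + shift, 0), 255)
}

#' Define a synthetic slide scenario
#'
#' A scenario is a rectangular zone layout over an `n_rows x n_cols` patch
#' grid. The first zone must cover the whole grid; later zones override
#' earlier ones where they overlap. Each zone has a kind (`"tissue"` or
#' `"background"`), an embedding class for the patch backend, a nucleus
#' density (cells/patch) and a cell-type mixture.
#'
#' @param n_rows,n_cols Grid size in patches.
#' @param cell_types Character vector of cell-type names.
#' @param zones Data frame: `name`, `row_min`, `row_max`, `col_min`,
#'   `col_max` (patch units, half-open), `kind`, `embed_class`, `density`.
#' @param mixtures Named list: zone name -> numeric mixture over
#'   `cell_types` (each summing to 1; ignored for background zones).
#' @param markers A [marker_set()] used to simulate counts and to classify
#'   them back; marker genes of a spot's true type are up-shifted.
#' @param marker_effect Mean multiplier for matching-type marker genes
#'   (default 6).
#' @param base_mu Baseline negative-binomial mean per gene (default 5,
#'   giving roughly 100 total counts per spot on the default panel, in line
#'   with near-single-cell binned spots).
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2;
#'   default 0.1, the near-Poisson regime of UMI-based counts).
#' @param spots_per_patch_side Spot lattice side per patch (default 2, i.e.
#'   4 spots/patch; 0 disables spot/count simulation).
#' @param n_filler_genes Non-marker genes added to the panel (default 8).
#' @param sigma_patch,sigma_nucleus Embedding noise sd for the patch and
#'   nucleus backends (default 0).
#' @param label_noise Per-type probability that a nucleus label is flipped
#'   to a random other type when `labels_from = "noisy"` in
#'   [recovery_experiment()]; scalar or named vector (default 0).
#' @param embed_dim Synthetic embedding dimension (default 32).
#' @param seed Integer seed; the whole slide is a deterministic function of
#'   the scenario including this seed.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_rows, n_cols, cell_types, zones, mixtures,
                               markers = load_marker_set("lung_colon"),
                               marker_effect = 6, base_mu = 5,
                               nb_dispersion = 0.1, spots_per_patch_side = 2L,
                               n_filler_genes = 8L, sigma_patch = 0,
                               sigma_nucleus = 0, label_noise = 0,
                               embed_dim = 32L, seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1, is.data.frame(zones))
  need <- c("name", "row_min", "row_max", "col_min", "col_max", "kind",
            "embed_class", "density")
  if (!all(need %in% names(zones))) stop("zones missing columns: ",
                                         paste(setdiff(need, names(zones)), collapse = ", "))
  z1 <- zones[1, ]
  if (z1$row_min != 0 || z1$col_min != 0 || z1$row_max < n_rows || z1$col_max < n_cols)
    stop("the first zone must cover the whole grid")
  if (any(zones$row_min < 0 | zones$col_min < 0 |
          zones$row_max > n_rows | zones$col_max > n_cols |
          zones$row_min >= zones$row_max | zones$col_min >= zones$col_max))
    stop("zone rectangles must be non-empty subsets of the grid")
  for (zn in zones$name[zones$kind == "tissue"]) {
    mx <- mixtures[[zn]]
    if (is.null(mx) || length(mx) != length(cell_types) ||
        abs(sum(mx) - 1) > 1e-8 || any(mx < 0))
      stop("mixture for zone '", zn, "' must be a non-negative vector over cell_types summing to 1")
  }
  if (length(label_noise) == 1L && is.null(names(label_noise)))
    label_noise <- setNames(rep(label_noise, length(cell_types)), cell_types)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_types = cell_types, zones = zones, mixtures = mixtures,
                 markers = markers, marker_effect = marker_effect,
                 base_mu = base_mu, nb_dispersion = nb_dispersion,
                 spots_per_patch_side = as.integer(spots_per_patch_side),
                 n_filler_genes = as.integer(n_filler_genes),
                 sigma_patch = sigma_patch, sigma_nucleus = sigma_nucleus,
                 label_noise = label_noise, embed_dim = as.integer(embed_dim),
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Scenario presets
#'
#' * `"margin"`: all-tissue slide split into a tumor-dominant side, a
#'   stromal side and a mixed margin band; noiseless embeddings. Windows
#'   straddling the margin carry the highest planted diversity.
#' * `"prostate_like"`: dense epithelial background with tumor nodules.
#' * `"lung_like"`: sparse cellularity with near-white background zones
#'   that exercise the tier-1 filter.
#' * `"complementary"`: four vertical strips where one zone interface is
#'   visible only to the visual arm (distinct embedding classes, labels
#'   noisy) and another only to the cellular arm (shared embedding class,
#'   labels clean), so the two score components carry complementary signal.
#'
#' @param name Preset name.
#' @param n Grid side in patches (default 40).
#' @param seed Integer seed.
#' @param ... Overrides passed to [synthetic_scenario()].
#' @return A `synthetic_scenario`.
#' @export
scenario_preset <- function(name = c("margin", "prostate_like", "lung_like",
                                     "complementary"),
                            n = 40L, seed = 1L, ...) {
  name <- match.arg(name)
  zone <- function(nm, r0, r1, c0, c1, kind, cls, dens)
    data.frame(name = nm, row_min = r0, row_max = r1, col_min = c0,
               col_max = c1, kind = kind, embed_class = cls, density = dens,
               stringsAsFactors = FALSE)
  args <- switch(name,
    margin = {
      b <- max(2L, round(n / 20))
      mid <- n %/% 2
      list(n_rows = n, n_cols = n,
           cell_types = c("tumor", "immune", "stromal"),
           zones = rbind(
             zone("core", 0, n, 0, n, "tissue", "tumor_region", 12),
             zone("margin", 0, n, mid - b, mid + b, "tissue", "margin_region", 12),
             zone("stroma", 0, n, mid + b, n, "tissue", "stroma_region", 12)),
           mixtures = list(core = c(0.85, 0.05, 0.10),
                           margin = c(0.45, 0.20, 0.35),
                           stroma = c(0.08, 0.12, 0.80)),
           sigma_patch = 0, sigma_nucleus = 0)
    },
    prostate_like = {
      q <- n %/% 4
      list(n_rows = n, n_cols = n,
           cell_types = c("tumor", "epithelial"),
           zones = rbind(
             zone("gland", 0, n, 0, n, "tissue", "gland_region", 20),
             zone("nodule1", q, 2 * q, q, 2 * q, "tissue", "tumor_nodule", 24),
             zone("nodule2", 2 * q, 3 * q, 2 * q, 3 * q, "tissue", "tumor_nodule", 24)),
           mixtures = list(gland = c(0.10, 0.90),
                           nodule1 = c(0.85, 0.15), nodule2 = c(0.85, 0.15)),
           markers = load_marker_set("prostate"),
           sigma_patch = 0.05, sigma_nucleus = 0.05)
    },
    lung_like = {
      h <- n %/% 2
      list(n_rows = n, n_cols = n,
           cell_types = c("tumor", "immune", "stromal"),
           zones = rbind(
             zone("air", 0, n, 0, n, "background", "background", 0),
             zone("parenchyma", 2, n - 2, 2, h, "tissue", "parenchyma_region", 5),
             zone("lesion", 2, n - 2, h, n - 2, "tissue", "tumor_lesion", 8)),
           mixtures = list(parenchyma = c(0.05, 0.25, 0.70),
                           lesion = c(0.60, 0.25, 0.15)),
           sigma_patch = 0.05, sigma_nucleus = 0.05)
    },
    complementary = {
      q <- n %/% 4
      list(n_rows = n, n_cols = n,
           cell_types = c("tumor", "immune", "stromal"),
           zones = rbind(
             zone("A", 0, n, 0, n, "tissue", "A_vis", 12),
             zone("B", 0, n, q, 2 * q, "tissue", "B_vis", 12),
             zone("C", 0, n, 2 * q, 3 * q, "tissue", "shared_vis", 12),
             zone("D", 0, n, 3 * q, n, "tissue", "shared_vis", 12)),
           mixtures = list(A = c(0.70, 0.20, 0.10), B = c(0.20, 0.70, 0.10),
                           C = c(0.20, 0.20, 0.60), D = c(0.00, 0.00, 1.00)),
           sigma_patch = 0.10, sigma_nucleus = 0.10,
           label_noise = c(tumor = 0.5, immune = 0.5, stromal = 0.02))
    })
  args$seed <- seed
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_scenario, args)
}

# zone index per patch (n_rows x n_cols), later zones override earlier ones
zone_map <- function(scn) {
  zm <- matrix(NA_integer_, scn$n_rows, scn$n_cols)
  for (z in seq_len(nrow(scn$zones))) {
    zz <- scn$zones[z, ]
    zm[(zz$row_min + 1):zz$row_max, (zz$col_min + 1):zz$col_max] <- z
  }
  zm
}

#' Generate a synthetic slide from a scenario
#'
#' Fully seeded: the same scenario yields bit-identical output.
#'
#' @param scn A [synthetic_scenario()].
#' @param cfg A [score_config()] used for the planted rankings' window
#'   lattice.
#' @return An object of class `synthetic_slide`: `grid` (filtered
#'   [build_grid()] lattice), `patch_zone` (zone index per patch,
#'   row-major), `patch_emb` (embeddings of retained patches),
#'   `patch_backend`, `nucleus_backend`, `nuclei` (labels unset),
#'   `truth_labels`, `spots`, `spot_truth`, `counts`, `sf`, `crop`,
#'   `planted` (list of `diversity` and, when a `tumor` type exists,
#'   `tumor` [region_ranking()]s), and the block data used by
#'   [realize_patch()].
#' @export
make_slide <- function(scn, cfg = score_config()) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(scn$seed)
  patch_px <- 224L
  zm <- zone_map(scn)
  n_patch <- scn$n_rows * scn$n_cols
  # row-major patch order (matches build_grid()$patches)
  pz <- as.integer(t(zm))
  is_bg_zone <- scn$zones$kind == "background"
  # distinct palette shift per tissue zone keeps zone textures distinguishable
  palettes <- lapply(seq_len(nrow(scn$zones)), function(z)
    if (is_bg_zone[z]) .palette_background()
    else .palette_tissue(shift = ((z * 37) %% 25) - 12))
  n_blocks <- BLOCKS_PER_SIDE^2
  block_idx <- matrix(0L, n_patch, n_blocks)
  stats <- data.frame(mean_gray = numeric(n_patch), std_gray = numeric(n_patch),
                      frac_bright_rgb = numeric(n_patch),
                      all_white = logical(n_patch), all_black = logical(n_patch))
  for (z in seq_len(nrow(scn$zones))) {
    sel <- which(pz == z)
    if (length(sel) == 0) next
    pal <- palettes[[z]]
    bi <- matrix(sample.int(nrow(pal), length(sel) * n_blocks, replace = TRUE),
                 length(sel), n_blocks)
    block_idx[sel, ] <- bi
    gray <- round(0.299 * pal[, 1] + 0.587 * pal[, 2] + 0.114 * pal[, 3])
    g <- matrix(gray[bi], length(sel), n_blocks)
    mu <- rowMeans(g)
    stats$mean_gray[sel] <- mu
    stats$std_gray[sel] <- sqrt(rowMeans((g - mu)^2))
    bright <- pmin(pal[, 1], pal[, 2], pal[, 3]) >= 230
    stats$frac_bright_rgb[sel] <- rowMeans(matrix(bright[bi], length(sel), n_blocks))
    white <- rowSums(pal == 255) == 3
    black <- rowSums(pal == 0) == 3
    stats$all_white[sel] <- rowSums(matrix(white[bi], length(sel), n_blocks)) == n_blocks
    stats$all_black[sel] <- rowSums(matrix(black[bi], length(sel), n_blocks)) == n_blocks
  }
  grid <- build_grid(scn$n_rows * patch_px, scn$n_cols * patch_px, patch_px)
  grid <- apply_filters(grid, stats)
  retained <- retained_patches(grid)

  patch_classes <- unique(scn$zones$embed_class)
  if (length(patch_classes) < 2)  # backend needs >= 2 prototypes
    patch_classes <- c(patch_classes, ".unused")
  patch_backend <- synthetic_backend(patch_classes,
                                     dim = scn$embed_dim, seed = scn$seed,
                                     sigma = scn$sigma_patch)
  patch_emb <- embed_patches(scn$zones$embed_class[pz[retained]], patch_backend,
                             sigma = scn$sigma_patch, seed = scn$seed + 1L)

  # ---- nuclei ---------------------------------------------------------------
  dens <- scn$zones$density[pz]
  n_per_patch <- rpois(n_patch, dens)
  patch_of <- rep.int(seq_len(n_patch), n_per_patch)
  n_nuc <- length(patch_of)
  truth <- character(n_nuc)
  for (z in which(!is_bg_zone)) {
    sel <- which(pz[patch_of] == z)
    if (length(sel))
      truth[sel] <- sample(scn$cell_types, length(sel), replace = TRUE,
                           prob = scn$mixtures[[scn$zones$name[z]]])
  }
  prow <- (patch_of - 1L) %/% scn$n_cols
  pcol <- (patch_of - 1L) %% scn$n_cols
  cy <- prow * patch_px + sample.int(patch_px, n_nuc, replace = TRUE) - 1L
  cx <- pcol * patch_px + sample.int(patch_px, n_nuc, replace = TRUE) - 1L
  nucleus_backend <- synthetic_backend(scn$cell_types, dim = scn$embed_dim,
                                       seed = scn$seed + 2L,
                                       sigma = scn$sigma_nucleus)
  nuc_emb <- embed_items(nucleus_backend, truth, sigma = scn$sigma_nucleus,
                         seed = scn$seed + 3L)
  nuclei <- nuclei_table(cy, cx, nuc_emb,
                         detection_prob = runif(n_nuc, 0.5, 1))

  # ---- spots and counts -----------------------------------------------------
  crop <- structure(list(row_min = 512L, row_max = 512L + scn$n_rows * patch_px,
                         col_min = 768L, col_max = 768L + scn$n_cols * patch_px),
                    class = "crop_bounds")
  sf <- scale_factors(0.274, 8 / 0.274)
  spots <- NULL; counts <- NULL; spot_truth <- NULL
  s <- scn$spots_per_patch_side
  if (s > 0) {
    off <- (seq_len(s) - 0.5) * patch_px / s
    g <- expand.grid(orow = off, ocol = off,
                     prow = 0:(scn$n_rows - 1L), pcol = 0:(scn$n_cols - 1L))
    sp_patch <- g$prow * scn$n_cols + g$pcol + 1L
    sp_zone <- pz[sp_patch]
    in_tissue <- !is_bg_zone[sp_zone]
    spot_truth <- rep(NA_character_, nrow(g))
    for (z in which(!is_bg_zone)) {
      sel <- which(sp_zone == z)
      if (length(sel))
        spot_truth[sel] <- sample(scn$cell_types, length(sel), replace = TRUE,
                                  prob = scn$mixtures[[scn$zones$name[z]]])
    }
    genes <- unique(c(toupper(unlist(scn$markers)),
                      sprintf("FILLER%02d", seq_len(scn$n_filler_genes))))
    mu <- matrix(scn$base_mu, length(genes), nrow(g),
                 dimnames = list(genes, NULL))
    for (ty in intersect(scn$cell_types, names(scn$markers))) {
      gsel <- match(toupper(scn$markers[[ty]]), genes)
      ssel <- which(!is.na(spot_truth) & spot_truth == ty)
      if (length(ssel)) mu[gsel, ssel] <- scn$base_mu * scn$marker_effect
    }
    size <- 1 / scn$nb_dispersion
    cnt <- matrix(rnbinom(length(mu), size = size, mu = as.vector(mu)),
                  nrow(mu), ncol(mu), dimnames = dimnames(mu))
    counts <- methods::as(Matrix::Matrix(cnt, sparse = TRUE), "CsparseMatrix")
    spot_ids <- sprintf("spot_%06d", seq_len(nrow(g)))
    colnames(counts) <- spot_ids
    spots <- spot_table(spot_ids,
                        crop$row_min + floor(g$prow * patch_px + g$orow),
                        crop$col_min + floor(g$pcol * patch_px + g$ocol),
                        in_tissue)
  }

  # ---- planted ground truth from true labels --------------------------------
  windows <- sliding_windows(grid, cfg)
  counts_by_type <- window_class_counts(grid, windows, prow, pcol, truth,
                                        scn$cell_types, cfg$window)
  planted <- list(diversity = region_ranking(
    data.frame(anchor_row = windows$anchor_row,
               anchor_col = windows$anchor_col,
               score = window_entropy_scores(counts_by_type, cfg$min_cells)),
    method = "planted_diversity"))
  if ("tumor" %in% scn$cell_types)
    planted$tumor <- region_ranking(
      data.frame(anchor_row = windows$anchor_row,
                 anchor_col = windows$anchor_col,
                 score = counts_by_type[, "tumor"]),
      method = "planted_tumor")

  structure(list(scenario = scn, grid = grid, patch_zone = pz,
                 patch_emb = patch_emb, patch_backend = patch_backend,
                 nucleus_backend = nucleus_backend, nuclei = nuclei,
                 truth_labels = truth, spots = spots, spot_truth = spot_truth,
                 counts = counts, sf = sf, crop = crop, planted = planted,
                 block_idx = block_idx, palettes = palettes),
            class = "synthetic_slide")
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("<synthetic_slide> %d x %d patches, %d nuclei, %s spots\n",
              x$grid$n_rows, x$grid$n_cols, n_nuclei(x$nuclei),
              ifelse(is.null(x$spots), "no", nrow(x$spots))))
  invisible(x)
}

#' Realize the full pixel array of one synthetic patch
#'
#' Expands the patch's 8x8 block colors into a `224 x 224 x 3` array whose
#' pixel statistics equal the block-level statistics stored in the grid.
#'
#' @param slide A [make_slide()] result.
#' @param row,col Patch coordinates (0-based).
#' @return `224 x 224 x 3` numeric array with values in \[0, 255\].
#' @export
realize_patch <- function(slide, row, col) {
  patch_px <- slide$grid$patch_px
  i <- patch_index(slide$grid, row, col)
  pal <- slide$palettes[[slide$patch_zone[i]]]
  bi <- matrix(slide$block_idx[i, ], BLOCKS_PER_SIDE, BLOCKS_PER_SIDE)
  bs <- patch_px %/% BLOCKS_PER_SIDE
  big <- bi[rep(seq_len(BLOCKS_PER_SIDE), each = bs),
            rep(seq_len(BLOCKS_PER_SIDE), each = bs)]
  array(c(pal[big, 1], pal[big, 2], pal[big, 3]),
        dim = c(patch_px, patch_px, 3))
}

#' Write a synthetic slide bundle to disk
#'
#' Writes the formats the I/O layer reads back: `scalefactors_json.json`,
#' `tissue_positions.parquet`, a `counts/` MTX triplet and `nuclei.h5`.
#'
#' @param slide A [make_slide()] result (with spots enabled).
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_slide_bundle <- function(slide, dir) {
  if (is.null(slide$spots)) stop("slide was generated without spots")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_scalefactors(slide$sf, file.path(dir, "scalefactors_json.json"))
  write_spot_positions(slide$spots, file.path(dir, "tissue_positions.parquet"))
  write_counts_mtx(slide$counts, file.path(dir, "counts"))
  write_nuclei(slide$nuclei, file.path(dir, "nuclei.h5"))
  invisible(dir)
}

#' Run the ranking-recovery experiment on a scenario
#'
#' For each seed: generate the slide, label nuclei (`"true"` uses the
#' planted labels; `"zero_shot"` labels from the noisy nucleus embeddings;
#' `"noisy"` flips each true label to a random other type with the
#' scenario's per-type `label_noise` probability), score every window, and
#' evaluate the resulting ranking against the planted ground truth.
#'
#' @param scn A [synthetic_scenario()] (grid at least the window size).
#' @param cfg A [score_config()]; `cfg$w` is used unless `w_grid` is given.
#' @param n_seeds Number of replicate slides (seeds `scn$seed + 0:(n-1)`).
#' @param mode `"diversity"` or `"targeted"` (targeted requires a `tumor`
#'   cell type and scores the prompt `"tumor"`).
#' @param labels_from `"true"`, `"zero_shot"` or `"noisy"`.
#' @param w_grid Optional vector of blend weights; component scores are
#'   computed once per slide and re-blended per weight.
#' @param overlap_frac Top fraction for the overlap metric (default 0.1).
#' @return Data frame: `seed`, `w`, `rho`, `overlap_pct`, `n_windows`.
#' @export
recovery_experiment <- function(scn, cfg = score_config(), n_seeds = 1L,
                                mode = c("diversity", "targeted"),
                                labels_from = c("true", "zero_shot", "noisy"),
                                w_grid = NULL, overlap_frac = 0.1) {
  mode <- match.arg(mode)
  labels_from <- match.arg(labels_from)
  if (is.null(w_grid)) w_grid <- cfg$w
  out <- list()
  for (s in seq_len(n_seeds)) {
    scn_s <- scn; scn_s$seed <- scn$seed + s - 1L
    slide <- make_slide(scn_s, cfg)
    nuclei <- slide$nuclei
    nuclei$info$label <- switch(labels_from,
      true = slide$truth_labels,
      zero_shot = {
        zs <- zero_shot_label(nuclei, label_set(scn$cell_types),
                              slide$nucleus_backend)
        zs$info$label
      },
      noisy = {
        lab <- slide$truth_labels
        old <- .Random.seed_save()
        set.seed(scn_s$seed + 7L)
        flip <- runif(length(lab)) < scn$label_noise[lab]
        if (any(flip))
          lab[flip] <- vapply(lab[flip], function(l)
            sample(setdiff(scn$cell_types, l), 1), character(1))
        .Random.seed_restore(old)
        lab
      })
    gt <- if (mode == "diversity") slide$planted$diversity else slide$planted$tumor
    scored <- if (mode == "diversity") {
      reduced <- reduce_embeddings(slide$patch_emb, cfg)
      score_diversity(slide$grid, reduced, nuclei, cfg)
    } else {
      text_emb <- embed_text("tumor", slide$patch_backend)
      score_targeted(slide$grid, slide$patch_emb, text_emb, nuclei, "tumor", cfg)
    }
    K <- max(1L, round(overlap_frac * nrow(gt)))
    for (w in w_grid) {
      comp <- if (mode == "diversity")
        diversity_score(scored$score_visual, scored$score_cellular, w)
      else targeted_score(scored$score_vlm, scored$score_count, w)
      rank <- region_ranking(data.frame(anchor_row = scored$anchor_row,
                                        anchor_col = scored$anchor_col,
                                        score = comp),
                             method = sprintf("%s_w%.1f", mode, w))
      out[[length(out) + 1L]] <- data.frame(
        seed = scn_s$seed, w = w,
        rho = spearman_common(rank, gt),
        overlap_pct = overlap_at_k(rank, gt, K),
        n_windows = nrow(gt))
    }
  }
  do.call(rbind, out)
}
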