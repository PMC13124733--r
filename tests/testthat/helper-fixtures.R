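# Shared fixture builders: everything is generated in code at test time.

# Constant-color patch (all three channels equal to `value` unless rgb given).
const_patch <- function(value = 255, size = 16L, rgb = NULL) {
  if (is.null(rgb)) rgb <- rep(value, 3)
  array(rep(rgb, each = size * size), dim = c(size, size, 3))
}

# Two-value checkerboard in all channels.
checker_patch <- function(a, b, size = 16L) {
  m <- outer(seq_len(size), seq_len(size), function(i, j) (i + j) %% 2)
  g <- ifelse(m == 1, a, b)
  array(rep(g, 3), dim = c(size, size, 3))
}

# Minimal separable nuclei table with planted truth.
planted_nuclei <- function(n, types, backend, sigma, seed, extent = 2240L) {
  set.seed(seed)
  truth <- sample(types, n, replace = TRUE)
  emb <- embed_items(backend, truth, sigma = sigma, seed = seed + 1L)
  list(nuclei = nuclei_table(sample.int(extent, n, TRUE) - 1L,
                             sample.int(extent, n, TRUE) - 1L, emb),
       truth = truth)
}

# Brute-force median pairwise Euclidean distance (independent oracle).
brute_median_pairdist <- function(M) {
  n <- nrow(M)
  if (n < 2) return(0)
  d <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    d <- c(d, sqrt(sum((M[i, ] - M[j, ])^2)))
  median(d)
}

# Brute-force rasterization of window sets into patch-cell matrices
# (independent oracle for overlap/IoU checks).
brute_raster <- function(rows, cols, window, extent) {
  M <- matrix(FALSE, extent, extent)
  for (i in seq_along(rows)) {
    M[rows[i] + seq_len(window), cols[i] + seq_len(window)] <- TRUE
  }
  M
}

# A tiny ranking data frame over an r x c anchor lattice with given scores.
tiny_ranking <- function(scores, n_side = NULL, method = "test") {
  if (is.null(n_side)) n_side <- ceiling(sqrt(length(scores)))
  g <- expand.grid(anchor_col = 0:(n_side - 1), anchor_row = 0:(n_side - 1))
  df <- data.frame(anchor_row = g$anchor_row[seq_along(scores)],
                   anchor_col = g$anchor_col[seq_along(scores)],
                   score = scores)
  region_ranking(df, method = method)
}
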