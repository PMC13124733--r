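# Embedding-backend contract and the built-in synthetic backend.
#
# Any provider must be deterministic for a fixed input (frozen-extractor
# semantics) and declare its embedding dimension. The synthetic backend
# assigns each class a row of a seeded random orthonormal basis as its
# prototype; an item of class k embeds as prototype_k plus isotropic
# Gaussian noise, and a text label embeds as its exact prototype. This makes
# within-/between-class cosine similarities exact at sigma = 0.

#' Cosine similarity between two vectors
#'
#' @param a,b Numeric vectors of equal length, each with at least one
#'   nonzero entry.
#' @return `sum(a*b) / (||a|| ||b||)`, in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

# Row-wise cosine similarity of matrix M against vector v.
cosine_sim_rows <- function(M, v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("cosine similarity undefined for a zero vector")
  nm <- sqrt(rowSums(M^2))
  if (any(nm == 0)) stop("cosine similarity undefined for a zero vector")
  as.numeric(M %*% v) / (nm * nv)
}

#' Deterministic synthetic embedding backend
#'
#' Builds a backend whose class prototypes are the first `n_classes` rows of
#' a seeded random orthonormal basis (so distinct prototypes are exactly
#' orthogonal). Items embed as their class prototype plus Gaussian noise of
#' standard deviation `sigma` per coordinate; text labels embed as the exact
#' prototype of the matching class.
#'
#' @param class_names Character vector of class names (>= 2).
#' @param dim Embedding dimension `D >= n_classes`.
#' @param seed Integer seed fixing the prototype basis.
#' @param sigma Default noise standard deviation for item embeddings.
#' @return An object of class `synthetic_backend`.
#' @export
synthetic_backend <- function(class_names, dim = 32L, seed = 1L, sigma = 0) {
  class_names <- as.character(class_names)
  n_classes <- length(class_names)
  if (n_classes < 2) stop("need at least 2 classes")
  if (anyDuplicated(class_names)) stop("class names must be unique")
  if (dim < n_classes) stop("embedding dimension must be >= number of classes")
  old <- .Random.seed_save()
  set.seed(seed)
  basis <- qr.Q(qr(matrix(rnorm(dim * dim), dim, dim)))
  .Random.seed_restore(old)
  prototypes <- t(basis[, seq_len(n_classes), drop = FALSE])
  rownames(prototypes) <- class_names
  structure(list(class_names = class_names, dim = as.integer(dim),
                 prototypes = prototypes, sigma = sigma, seed = as.integer(seed)),
            class = "synthetic_backend")
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Embed items of known class with a synthetic backend
#'
#' @param backend A [synthetic_backend()].
#' @param classes Character vector of class names, one per item.
#' @param sigma Noise sd (defaults to the backend's).
#' @param seed Integer seed for the noise draw; the same seed and input give
#'   bit-identical output.
#' @return `N x D` embedding matrix.
#' @export
embed_items <- function(backend, classes, sigma = backend$sigma, seed = 1L) {
  stopifnot(inherits(backend, "synthetic_backend"))
  idx <- match(classes, backend$class_names)
  if (anyNA(idx)) stop("unknown class: ", paste(unique(classes[is.na(idx)]), collapse = ", "))
  E <- backend$prototypes[idx, , drop = FALSE]
  if (sigma > 0) {
    old <- .Random.seed_save()
    set.seed(seed)
    E <- E + matrix(rnorm(length(E), sd = sigma), nrow(E), ncol(E))
    .Random.seed_restore(old)
  }
  rownames(E) <- NULL
  E
}

#' Embed patches through a backend
#'
#' For the synthetic backend, patches are identified by their planted class
#' labels. Validates the backend contract: one vector per patch, declared
#' dimension, no non-finite entries.
#'
#' @param patches Character vector of per-patch classes (synthetic backend).
#' @param backend A backend object.
#' @param sigma,seed Passed to [embed_items()].
#' @return `N x D` embedding matrix.
#' @export
embed_patches <- function(patches, backend, sigma = backend$sigma, seed = 1L) {
  E <- embed_items(backend, patches, sigma = sigma, seed = seed)
  if (ncol(E) != backend$dim)
    stop("backend returned dimension ", ncol(E), ", declared ", backend$dim)
  if (any(!is.finite(E))) stop("backend returned non-finite embedding values")
  E
}

#' Embed a text prompt through a backend
#'
#' The synthetic backend maps a prompt to the prototype of the class whose
#' name it contains (exact name match first, then substring match).
#'
#' @param prompt Non-empty character string.
#' @param backend A backend object.
#' @return Numeric `D`-vector.
#' @export
embed_text <- function(prompt, backend) {
  stopifnot(inherits(backend, "synthetic_backend"))
  if (!is.character(prompt) || length(prompt) != 1L || !nzchar(prompt))
    stop("prompt must be a non-empty string")
  k <- match(prompt, backend$class_names)
  if (is.na(k)) {
    hits <- which(vapply(backend$class_names, function(cl)
      grepl(cl, prompt, fixed = TRUE) || grepl(prompt, cl, fixed = TRUE),
      logical(1)))
    if (length(hits) == 0)
      stop("prompt matches no class known to the synthetic backend: ", prompt)
    k <- hits[1]
  }
  as.numeric(backend$prototypes[k, ])
}
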