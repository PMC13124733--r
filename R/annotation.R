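# Nucleus cell-type annotation: zero-shot labeling from a joint image-text
# embedding space, followed by iterative supervised refinement with a
# gradient-boosted classifier trained on cumulative expert annotations.

#' Ordered set of cell-type labels
#'
#' @param names Character vector of 2-10 unique class names.
#' @param target_class Optional class used by targeted scoring (must be a
#'   member of `names`).
#' @return An object of class `label_set`.
#' @export
label_set <- function(names, target_class = NULL) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("label names must be unique")
  if (length(names) < 2 || length(names) > 10)
    stop("a label set must contain between 2 and 10 classes")
  if (!is.null(target_class) && !target_class %in% names)
    stop("target_class must be one of the label names")
  structure(list(names = names, target_class = target_class), class = "label_set")
}

# argmax over rows with ties broken by the lowest class index.
argmax_first <- function(M) max.col(M, ties.method = "first")

#' Zero-shot cell-type labeling
#'
#' Embeds each label name through the backend's text encoder and assigns
#' every nucleus the label with the highest cosine similarity to its image
#' embedding. Ties break to the lowest class index in label-set order.
#'
#' @param nuclei A [nuclei_table()].
#' @param labels A [label_set()].
#' @param backend An embedding backend sharing the nuclei's dimension.
#' @return The nuclei table with `info$label` filled; the similarity matrix
#'   is attached as attribute `similarity`.
#' @export
zero_shot_label <- function(nuclei, labels, backend) {
  stopifnot(inherits(nuclei, "nuclei_table"), inherits(labels, "label_set"))
  if (length(labels$names) == 0) stop("empty label set")
  text_emb <- vapply(labels$names, embed_text, numeric(backend$dim), backend = backend)
  sims <- vapply(seq_len(ncol(text_emb)), function(k)
    cosine_sim_rows(nuclei$embedding, text_emb[, k]), numeric(n_nuclei(nuclei)))
  sims <- matrix(sims, nrow = n_nuclei(nuclei))
  colnames(sims) <- labels$names
  nuclei$info$label <- labels$names[argmax_first(sims)]
  attr(nuclei, "similarity") <- sims
  nuclei
}

#' Train the supervised nucleus classifier on cumulative annotations
#'
#' Fits a gradient-boosted multiclass model (100 trees, depth 6, learning
#' rate 0.3, softprob objective) on the `(embedding, label)` pairs of the
#' annotated nuclei. Deterministic for a fixed seed.
#'
#' @param annotations Data frame with columns `nucleus_id` and `label`
#'   (the cumulative annotation set; later entries for the same nucleus
#'   override earlier ones).
#' @param nuclei A [nuclei_table()] providing the embeddings.
#' @param labels A [label_set()] fixing the class universe and order.
#' @param seed Integer seed.
#' @return An object of class `nucleus_classifier`.
#' @export
train_classifier <- function(annotations, nuclei, labels, seed = 1L) {
  stopifnot(inherits(nuclei, "nuclei_table"), inherits(labels, "label_set"))
  if (nrow(annotations) == 0) stop("no annotations to train on")
  ann <- annotations[!duplicated(annotations$nucleus_id, fromLast = TRUE), , drop = FALSE]
  present <- unique(ann$label)
  if (length(present) < 2)
    stop("training set contains a single class; annotate at least one more class")
  if (!all(present %in% labels$names)) stop("annotation label outside the label set")
  ridx <- match(ann$nucleus_id, nuclei$info$nucleus_id)
  if (anyNA(ridx)) stop("annotation references unknown nucleus_id")
  X <- nuclei$embedding[ridx, , drop = FALSE]
  y <- match(ann$label, labels$names) - 1L
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob",
                  num_class = length(labels$names),
                  max_depth = 6, eta = 0.3, nthread = 1, seed = seed),
    data = dtrain, nrounds = 100, verbose = 0)
  structure(list(booster = booster, labels = labels, dim = ncol(X),
                 n_train = nrow(ann), seed = as.integer(seed)),
            class = "nucleus_classifier")
}

#' Apply a trained classifier to all nuclei
#'
#' @param state A [train_classifier()] result.
#' @param nuclei A [nuclei_table()] with matching embedding dimension.
#' @return The nuclei table with `info$label` set to the argmax-probability
#'   class (ties to the lowest class index); the `N x n_classes` probability
#'   matrix is attached as attribute `probabilities`.
#' @export
apply_classifier <- function(state, nuclei) {
  stopifnot(inherits(state, "nucleus_classifier"), inherits(nuclei, "nuclei_table"))
  if (ncol(nuclei$embedding) != state$dim)
    stop("embedding dimension mismatch: classifier expects ", state$dim)
  if (n_nuclei(nuclei) == 0) return(nuclei)
  probs <- predict(state$booster,
                   xgboost::xgb.DMatrix(nuclei$embedding, nthread = 1))
  probs <- matrix(probs, nrow = n_nuclei(nuclei))
  colnames(probs) <- state$labels$names
  nuclei$info$label <- state$labels$names[argmax_first(probs)]
  attr(nuclei, "probabilities") <- probs
  nuclei
}

#' Simulated annotator backed by planted truth
#'
#' Stands in for the expert: queried with a set of nucleus ids, it returns
#' their planted true labels, each independently replaced by a uniformly
#' random other class with probability `mislabel_rate`. An optional
#' per-cycle `focus` restricts early cycles to nuclei of a single true
#' class, emulating an annotator working one cell type at a time.
#'
#' @param truth Character vector of true labels indexed by position in the
#'   nuclei table.
#' @param labels A [label_set()].
#' @param mislabel_rate Probability of an incorrect label per nucleus.
#' @param focus Optional character vector; `focus[cycle]` (when not `NA`)
#'   keeps only queried nuclei whose true class equals it.
#' @return A function `(query_rows, cycle)` returning a data frame with
#'   columns `row` and `label` (possibly fewer rows than queried).
#' @export
simulated_annotator <- function(truth, labels, mislabel_rate = 0, focus = NULL) {
  force(truth); force(labels); force(mislabel_rate); force(focus)
  function(query_rows, cycle) {
    if (!is.null(focus) && cycle <= length(focus) && !is.na(focus[cycle]))
      query_rows <- query_rows[truth[query_rows] == focus[cycle]]
    lab <- truth[query_rows]
    if (mislabel_rate > 0 && length(lab) > 0) {
      flip <- runif(length(lab)) < mislabel_rate
      if (any(flip))
        lab[flip] <- vapply(lab[flip], function(l)
          sample(setdiff(labels$names, l), 1), character(1))
    }
    data.frame(row = query_rows, label = lab, stringsAsFactors = FALSE)
  }
}

#' Run an active-learning annotation session
#'
#' Starts from zero-shot labels. Each cycle selects a batch of unannotated
#' nuclei (by default the most uncertain under the current model), obtains
#' labels from the annotator, retrains the classifier on the cumulative
#' annotation set, and relabels every nucleus. The per-cycle log records
#' accuracy against planted truth (when supplied) and the cumulative
#' annotation count.
#'
#' @param nuclei A [nuclei_table()].
#' @param labels A [label_set()].
#' @param backend Embedding backend for the zero-shot start.
#' @param annotator A callable as returned by [simulated_annotator()].
#' @param n_cycles Number of annotation cycles.
#' @param budget_per_cycle Nuclei queried per cycle.
#' @param seed Integer seed covering query sampling and classifier fits.
#' @param truth Optional character vector of planted true labels (for the
#'   accuracy log only; never used for training).
#' @param query `"uncertainty"` (lowest top-class margin first, default) or
#'   `"random"`.
#' @return List: `state` (final classifier or `NULL` if never trainable),
#'   `nuclei` (relabeled), `log` (data frame: `cycle`, `n_new`,
#'   `n_cumulative`, `accuracy`). Cycle 0 is the zero-shot state. A zero
#'   budget or zero cycles returns the zero-shot labeling with an empty log.
#' @export
active_learning_session <- function(nuclei, labels, backend, annotator,
                                    n_cycles = 10L, budget_per_cycle = 30L,
                                    seed = 1L, truth = NULL,
                                    query = c("uncertainty", "random")) {
  query <- match.arg(query)
  nuclei <- zero_shot_label(nuclei, labels, backend)
  acc <- function(lab) if (is.null(truth)) NA_real_ else mean(lab == truth)
  if (n_cycles < 1 || budget_per_cycle < 1) {
    return(list(state = NULL, nuclei = nuclei,
                log = data.frame(cycle = integer(), n_new = integer(),
                                 n_cumulative = integer(), accuracy = numeric())))
  }
  sims <- attr(nuclei, "similarity")
  # uncertainty of the zero-shot assignment: negative top-two cosine margin
  margin <- function(M) {
    top2 <- t(apply(M, 1, function(r) sort(r, decreasing = TRUE)[1:2]))
    top2[, 1] - top2[, 2]
  }
  uncertainty <- -margin(sims)
  log_df <- data.frame(cycle = 0L, n_new = 0L, n_cumulative = 0L,
                       accuracy = acc(nuclei$info$label))
  annotations <- data.frame(nucleus_id = integer(), label = character(),
                            stringsAsFactors = FALSE)
  state <- NULL
  set.seed(seed)
  for (cyc in seq_len(n_cycles)) {
    pool <- setdiff(seq_len(n_nuclei(nuclei)),
                    match(annotations$nucleus_id, nuclei$info$nucleus_id))
    if (length(pool) == 0) break
    # round before ranking so floating-point noise among effectively tied
    # uncertainties does not bias selection; ties then break at random
    ord <- if (query == "uncertainty")
      pool[order(-round(uncertainty[pool], 9), sample.int(length(pool)))]
    else sample(pool)
    batch_rows <- head(ord, budget_per_cycle)
    got <- annotator(batch_rows, cyc)
    if (nrow(got) > 0) {
      annotations <- rbind(annotations, data.frame(
        nucleus_id = nuclei$info$nucleus_id[got$row], label = got$label,
        stringsAsFactors = FALSE))
    }
    if (length(unique(annotations$label)) >= 2) {
      state <- train_classifier(annotations, nuclei, labels, seed = seed + cyc)
      nuclei <- apply_classifier(state, nuclei)
      probs <- attr(nuclei, "probabilities")
      uncertainty <- -margin(probs)
    }
    log_df <- rbind(log_df, data.frame(cycle = cyc, n_new = nrow(got),
                                       n_cumulative = nrow(annotations),
                                       accuracy = acc(nuclei$info$label)))
  }
  list(state = state, nuclei = nuclei, log = log_df)
}
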