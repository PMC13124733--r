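types3 <- c("tumor", "immune", "stromal")

test_that("zero-shot labeling agrees with planted classes when noise is zero", {
  be <- synthetic_backend(types3, dim = 16, seed = 1, sigma = 0)
  nt <- planted_nuclei(300, types3, be, sigma = 0, seed = 2)
  out <- zero_shot_label(nt$nuclei, label_set(types3), be)
  expect_identical(out$info$label, nt$truth)
  sims <- attr(out, "similarity")
  expect_identical(dim(sims), c(300L, 3L))
})

test_that("zero-shot labeling is above chance under embedding noise", {
  be <- synthetic_backend(types3, dim = 16, seed = 1, sigma = 0.2)
  nt <- planted_nuclei(300, types3, be, sigma = 0.2, seed = 5)
  out <- zero_shot_label(nt$nuclei, label_set(types3), be)
  expect_gt(mean(out$info$label == nt$truth), 1 / 3)
})

test_that("the label set enforces its class-count and uniqueness invariants", {
  expect_error(label_set("tumor"), "between 2 and 10")
  expect_error(label_set(c("a", "a")), "unique")
  expect_error(label_set(letters[1:11]), "between 2 and 10")
  expect_error(label_set(c("a", "b"), target_class = "c"), "target_class")
})

test_that("the classifier separates planted classes and validates its inputs", {
  be <- synthetic_backend(types3, dim = 16, seed = 3, sigma = 0.05)
  nt <- planted_nuclei(50, types3, be, sigma = 0.05, seed = 4)
  ls <- label_set(types3)
  ann <- data.frame(nucleus_id = nt$nuclei$info$nucleus_id,
                    label = nt$truth)
  st <- train_classifier(ann, nt$nuclei, ls, seed = 1)
  out <- apply_classifier(st, nt$nuclei)
  expect_identical(out$info$label, nt$truth)      # separable: training acc 1
  probs <- attr(out, "probabilities")
  expect_equal(rowSums(probs), rep(1, 50), tolerance = 1e-6)

  # degenerate input tolerated: identical embeddings, different labels
  dup <- nuclei_table(c(0L, 0L), c(0L, 0L),
                      rbind(nt$nuclei$embedding[1, ], nt$nuclei$embedding[1, ]),
                      nucleus_id = c(0L, 1L))
  ann2 <- data.frame(nucleus_id = c(0L, 1L), label = c("tumor", "immune"))
  st2 <- train_classifier(ann2, dup, ls, seed = 1)
  out2 <- apply_classifier(st2, dup)
  expect_true(all(out2$info$label %in% c("tumor", "immune")))

  # single-class training set is an explicit error
  expect_error(train_classifier(ann[nt$truth == "tumor", ], nt$nuclei, ls),
               "single class")
  # dimension mismatch caught on apply
  small <- nuclei_table(0L, 0L, matrix(rnorm(4), 1, 4))
  expect_error(apply_classifier(st, small), "dimension mismatch")
})

test_that("training is deterministic for a fixed seed", {
  be <- synthetic_backend(types3, dim = 16, seed = 3, sigma = 0.3)
  nt <- planted_nuclei(120, types3, be, sigma = 0.3, seed = 8)
  ls <- label_set(types3)
  ann <- data.frame(nucleus_id = nt$nuclei$info$nucleus_id[1:60],
                    label = nt$truth[1:60])
  l1 <- apply_classifier(train_classifier(ann, nt$nuclei, ls, seed = 5),
                         nt$nuclei)$info$label
  l2 <- apply_classifier(train_classifier(ann, nt$nuclei, ls, seed = 5),
                         nt$nuclei)$info$label
  expect_identical(l1, l2)
})

test_that("an active-learning session never discards annotations and logs cycles", {
  be <- synthetic_backend(types3, dim = 16, seed = 6, sigma = 0.3)
  nt <- planted_nuclei(600, types3, be, sigma = 0.3, seed = 7)
  ls <- label_set(types3)
  ann <- simulated_annotator(nt$truth, ls)
  sess <- active_learning_session(nt$nuclei, ls, be, ann, n_cycles = 5,
                                  budget_per_cycle = 25, seed = 3,
                                  truth = nt$truth)
  expect_identical(sess$log$cycle, 0:5)
  expect_true(all(diff(sess$log$n_cumulative) >= 0))
  expect_identical(sess$log$n_cumulative[6], 125L)
  expect_s3_class(sess$state, "nucleus_classifier")

  # zero budget returns the zero-shot state with an empty log
  sess0 <- active_learning_session(nt$nuclei, ls, be, ann, n_cycles = 5,
                                   budget_per_cycle = 0, seed = 3)
  expect_null(sess0$state)
  expect_identical(nrow(sess0$log), 0L)
})

test_that("noiseless sessions hold accuracy 1 from the zero-shot start", {
  be <- synthetic_backend(types3, dim = 16, seed = 2, sigma = 0)
  nt <- planted_nuclei(200, types3, be, sigma = 0, seed = 3)
  ls <- label_set(types3)
  sess <- active_learning_session(nt$nuclei, ls, be,
                                  simulated_annotator(nt$truth, ls),
                                  n_cycles = 3, budget_per_cycle = 30,
                                  seed = 1, truth = nt$truth)
  expect_true(all(sess$log$accuracy == 1))
})

test_that("refinement beats zero-shot on noisy embeddings (mean over 5 seeds)", {
  ls <- label_set(types3)
  zero_shot_acc <- numeric(5); final_acc <- numeric(5)
  for (s in 1:5) {
    be <- synthetic_backend(types3, dim = 32, seed = 100 + s, sigma = 0.3)
    nt <- planted_nuclei(800, types3, be, sigma = 0.3, seed = 200 + s)
    sess <- active_learning_session(nt$nuclei, ls, be,
                                    simulated_annotator(nt$truth, ls),
                                    n_cycles = 10, budget_per_cycle = 30,
                                    seed = s, truth = nt$truth)
    zero_shot_acc[s] <- sess$log$accuracy[1]
    final_acc[s] <- sess$log$accuracy[nrow(sess$log)]
  }
  expect_gt(mean(final_acc), mean(zero_shot_acc))
})

test_that("a class-focused annotator can dip mid-session but ends at or above zero-shot", {
  ls <- label_set(types3)
  be <- synthetic_backend(types3, dim = 32, seed = 31, sigma = 0.3)
  nt <- planted_nuclei(800, types3, be, sigma = 0.3, seed = 32)
  focus <- c("tumor", "tumor", "tumor", rep(NA, 7))
  ann <- simulated_annotator(nt$truth, ls, focus = focus)
  sess <- active_learning_session(nt$nuclei, ls, be, ann, n_cycles = 10,
                                  budget_per_cycle = 30, seed = 2,
                                  truth = nt$truth)
  n <- nrow(sess$log)
  expect_gte(sess$log$accuracy[n], sess$log$accuracy[1])
})
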