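test_that("ROC endpoints, monotonicity, and degenerate inputs behave", {
  r <- roc_curve_auc(c(3, 2, 1, 0.5), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(r$roc_points$fpr[1], 0)
  expect_equal(r$roc_points$tpr[1], 0)
  expect_equal(unlist(r$roc_points[nrow(r$roc_points), ]),
               c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$roc_points$fpr) >= 0))
  expect_true(all(diff(r$roc_points$tpr) >= 0))
  # symmetry under score negation
  withr::with_seed(5, {
    sc <- rnorm(200); y <- rep(c(TRUE, FALSE), 100)
  })
  expect_equal(roc_curve_auc(-sc, y)$auc, 1 - roc_curve_auc(sc, y)$auc,
               tolerance = 1e-12)
  # constant scores: warning, AUC 0.5
  expect_warning(rc <- roc_curve_auc(rep(1, 10), rep(c(TRUE, FALSE), 5)),
                 "constant")
  expect_equal(rc$auc, 0.5)
  expect_error(roc_curve_auc(1:3, c(TRUE, TRUE, TRUE)), "positive and")
})

test_that("trapezoidal AUC equals the Mann-Whitney formulation", {
  withr::with_seed(42, {
    for (i in 1:100) {
      n <- sample(5:30, 1)
      sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
      y <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (sum(y) == 0 || sum(!y) == 0) next
      expect_equal(roc_curve_auc(sc, y)$auc, auc_mann_whitney(sc, y),
                   tolerance = 1e-9)
    }
  })
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    sc <- rnorm(300)
    y <- sc + rnorm(300) > 0
  })
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = sc,
                                        quiet = TRUE, direction = "<")))
  expect_equal(roc_curve_auc(sc, y)$auc, ref, tolerance = 1e-9)
})

test_that("confusion metrics match hand computations", {
  truth <- rep(c("pos", "neg"), c(10, 10))
  pred <- c(rep("pos", 9), "neg", rep("neg", 8), "pos", "pos")
  m <- compute_metrics(truth, pred, positive_class = "pos")
  expect_equal(unname(m), c(90, 80, 85))
  perfect <- compute_metrics(truth, truth, positive_class = "pos")
  expect_equal(unname(perfect), c(100, 100, 100))
  all_pos <- compute_metrics(truth, rep("pos", 20), positive_class = "pos")
  expect_equal(unname(all_pos[1:2]), c(100, 0))
  # metrics invariant to row order
  o <- sample(20)
  expect_equal(compute_metrics(truth[o], pred[o], positive_class = "pos"), m)
  # macro average warns about classes absent from truth
  expect_warning(compute_metrics(c("a", "a", "b", "b"), c("a", "c", "b", "b")),
                 "absent")
})

test_that("SVM cross-validation hits the ceiling on separable classes", {
  coh <- separable_cohort(n_per_class = 100, seed = 13)
  rep <- train_task(coh, "control_vs_disease", c("BVT_S", "FAZ_A_S"), seed = 1)
  expect_gte(rep$accuracy, 99)
  expect_gte(rep$auc, 0.999)
  # reproducible under the same seed
  rep2 <- train_task(coh, "control_vs_disease", c("BVT_S", "FAZ_A_S"), seed = 1)
  expect_equal(rep$accuracy, rep2$accuracy)
  expect_identical(rep$fold_assignments, rep2$fold_assignments)
})

test_that("permuted labels give chance-level accuracy", {
  accs <- vapply(1:10, function(s) {
    coh <- synthetic_cohort(n_per_class = 100, effect = 0, seed = 500 + s)
    train_task(coh, "control_vs_disease", c("BVT_S", "FAZ_A_S"),
               seed = s)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 5)
})

test_that("three-class SVM beats chance by a wide margin on ordered means", {
  coh <- synthetic_cohort(n_per_class = 60, effect = 0, seed = 19,
                          labels = c("mild_npdr", "moderate_npdr", "severe_npdr"))
  withr::with_seed(20, {
    coh$BVD_SC3 <- rnorm(nrow(coh)) + 2 * (coh$label == "moderate_npdr") +
      4 * (coh$label == "severe_npdr")
    coh$FAZ_A_S <- rnorm(nrow(coh)) + 2 * (coh$label == "moderate_npdr") +
      4 * (coh$label == "severe_npdr")
  })
  rep <- train_task(coh, "npdr_staging", c("BVD_SC3", "FAZ_A_S"), seed = 2)
  expect_gte(rep$accuracy, 33.3 + 40)
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  expect_true("class" %in% names(rep$roc_points))
})

test_that("fold assignment is stratified, subject-grouped, and shrinks when needed", {
  coh <- synthetic_cohort(n_per_class = 20, effect = 1, seed = 23)
  # both eyes of one subject share a fold
  coh2 <- dplyr::bind_rows(coh, dplyr::mutate(coh, eye = "OS"))
  rep <- train_task(coh2, "control_vs_disease", "BVT_S", seed = 1)
  fa <- rep$fold_assignments
  per_subject <- tapply(fa$fold, fa$subject_id, function(x) length(unique(x)))
  expect_true(all(per_subject == 1))
  # class smaller than fold count: folds reduced with a warning
  small <- synthetic_cohort(n_per_class = 3, effect = 4, seed = 29)
  expect_warning(rep3 <- train_task(small, "control_vs_disease", "BVT_S"),
                 "reducing")
  expect_lt(rep3$folds, 5)
  # single-class cohort errors
  ctl <- synthetic_cohort(n_per_class = 10, labels = "control", seed = 1)
  expect_error(train_task(ctl, "control_vs_disease", "BVT_S"), "single-class")
})

test_that("the hierarchy routes every input to exactly one leaf", {
  labels6 <- octa_labels()
  coh <- synthetic_cohort(n_per_class = 25, effect = 0, seed = 31,
                          labels = labels6)
  withr::with_seed(32, {
    # give each label a distinctive signature on three features
    mu <- stats::setNames(seq(0, 25, by = 5), labels6)
    coh$BVT_S <- rnorm(nrow(coh), mu[coh$label], 0.5)
    coh$BVD_SC3 <- rnorm(nrow(coh), rev(mu)[match(coh$label, labels6)], 0.5)
    coh$FAZ_A_S <- rnorm(nrow(coh), mu[coh$label]^1.5, 0.5)
  })
  feature_sets <- stats::setNames(
    rep(list(c("BVT_S", "BVD_SC3", "FAZ_A_S")), 4), octa_tasks())
  hier <- assemble_hierarchy(coh, feature_sets)
  pred <- predict(hier, coh)
  expect_true(all(!is.na(pred$leaf)))
  expect_true(all(pred$leaf %in% labels6))
  expect_gte(mean(pred$leaf == coh$label), 0.9)
  # control rows stop at stage 1
  expect_true(all(is.na(pred$stage2[pred$stage1 == "control"])))
  # missing stage model errors
  expect_error(assemble_hierarchy(coh, feature_sets[1:3]), "missing stage")
})
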