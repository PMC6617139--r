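test_that("univariate profile chooses tests by normality and applies Bonferroni", {
  coh <- synthetic_cohort(n_per_class = 50, effect = 3, seed = 11)
  prof <- univariate_profile(coh, "control_vs_disease")
  expect_equal(nrow(prof), 13)
  expect_true(all(prof$p_adjusted >= prof$p_value - 1e-12))
  expect_true(all(prof$p_adjusted <= 1))
  # informative features significant after correction, most noise not
  expect_lt(max(prof$p_adjusted[prof$feature %in% c("BVT_S", "FAZ_A_S")]), 0.001)
  expect_gt(median(prof$p_adjusted[!prof$feature %in% c("BVT_S", "FAZ_A_S")]), 0.2)
  sp <- attr(prof, "spearman")
  expect_equal(dim(sp), c(13, 13))
  expect_equal(unname(diag(sp)), rep(1, 13))
  # Bonferroni arithmetic: capped at 1
  expect_equal(min(1, 0.2 * 13), 1)
  # zero-variance group forces the nonparametric path
  coh2 <- coh
  coh2$VPI_S[coh2$label == "control"] <- 0.5
  prof2 <- univariate_profile(coh2, "control_vs_disease")
  row <- prof2[prof2$feature == "VPI_S", ]
  expect_match(row$note, "zero-variance")
  expect_false(row$normal)
})

test_that("null features yield mostly non-significant adjusted p-values", {
  coh <- synthetic_cohort(n_per_class = 50, effect = 0, seed = 3)
  prof <- univariate_profile(coh, "control_vs_disease")
  expect_gte(mean(prof$p_adjusted > 0.05), 0.9)
})

test_that("univariate screen keeps informative features and flags separation", {
  coh <- synthetic_cohort(n_per_class = 60, effect = 2, seed = 7)
  scr <- univariate_screen(coh, "control_vs_disease")
  expect_true(all(c("BVT_S", "FAZ_A_S") %in% scr$feature[scr$keep]))
  # constant feature: excluded
  coh$VPI_S <- 1
  scr2 <- univariate_screen(coh, "control_vs_disease")
  expect_false(scr2$keep[scr2$feature == "VPI_S"])
  # perfectly separating feature: kept with separation flag
  coh$BVC_S <- ifelse(coh$label == "control", 0, 10)
  scr3 <- univariate_screen(coh, "control_vs_disease")
  row <- scr3[scr3$feature == "BVC_S", ]
  expect_true(row$keep)
  expect_true(row$separation)
  expect_lte(row$p_value, .Machine$double.eps)
})

test_that("screen recovers informative features over repeated simulations", {
  hits <- 0
  n_runs <- 20
  for (s in seq_len(n_runs)) {
    coh <- synthetic_cohort(n_per_class = 60, effect = 2, seed = 100 + s)
    scr <- univariate_screen(coh, "control_vs_disease")
    if (all(c("BVT_S", "FAZ_A_S") %in% scr$feature[scr$keep])) hits <- hits + 1
  }
  expect_gte(hits / n_runs, 0.95)
})

test_that("backward elimination keeps a significant single candidate untouched", {
  coh <- synthetic_cohort(n_per_class = 60, effect = 2, seed = 21)
  tr <- backward_eliminate(coh, "control_vs_disease", "BVT_S")
  expect_equal(tr$retained, "BVT_S")
  expect_equal(nrow(tr$steps), 0)
  expect_false(tr$all_eliminated)
  expect_true(all(tr$retained_p$p_value < 0.05))
})

test_that("elimination is deterministic and never retains screened-out features", {
  coh <- synthetic_cohort(n_per_class = 60, effect = 2, seed = 33)
  tr1 <- select_features(coh, "control_vs_disease", seed = 4)
  tr2 <- select_features(coh, "control_vs_disease", seed = 4)
  expect_identical(tr1$retained, tr2$retained)
  expect_identical(tidy(tr1), tidy(tr2))
  scr <- attr(tr1, "screen")
  expect_true(all(tr1$retained %in% scr$feature[scr$keep]))
})

test_that("per-feature accuracy behaves at the ceiling and at chance", {
  coh <- synthetic_cohort(n_per_class = 40, effect = 0, seed = 2)
  # perfectly separating feature
  coh$BVT_S <- ifelse(coh$label == "control", 0, 10)
  expect_equal(per_feature_accuracy(coh, "control_vs_disease", "BVT_S"), 100)
  # label + small noise
  coh$BVC_S <- ifelse(coh$label == "control", 0, 1) + rnorm(nrow(coh), 0, 0.1)
  expect_gt(per_feature_accuracy(coh, "control_vs_disease", "BVC_S"), 95)
  # independent feature near chance (averaged over seeds)
  accs <- vapply(1:10, function(s) {
    coh2 <- synthetic_cohort(n_per_class = 100, effect = 0, seed = 300 + s)
    per_feature_accuracy(coh2, "control_vs_disease", "VPI_S", seed = s)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 5)
})

test_that("retained-set accuracy is not materially below the best single feature", {
  coh <- synthetic_cohort(n_per_class = 60, effect = 1.5,
                          informative = c("BVT_S", "FAZ_A_S", "BVD_SC3"),
                          seed = 17)
  tr <- select_features(coh, "control_vs_disease", seed = 3)
  rep <- train_task(coh, "control_vs_disease", tr$retained, seed = 3)
  best_single <- max(tr$per_feature_accuracy$accuracy)
  expect_gte(rep$accuracy, best_single - 5)
})

test_that("three-class staging uses the multinomial path", {
  coh <- synthetic_cohort(n_per_class = 40, effect = 0, seed = 9,
                          labels = c("mild_npdr", "moderate_npdr", "severe_npdr"))
  coh$BVD_SC3 <- rnorm(nrow(coh)) +
    2 * (coh$label == "moderate_npdr") + 4 * (coh$label == "severe_npdr")
  scr <- univariate_screen(coh, "npdr_staging")
  expect_true(scr$keep[scr$feature == "BVD_SC3"])
  tr <- backward_eliminate(coh, "npdr_staging", scr$feature[scr$keep])
  expect_true("BVD_SC3" %in% tr$retained)
})
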