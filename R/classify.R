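#' ROC curve and area under it
#'
#' Sweeps the decision threshold over the unique scores, collapsing ties, and
#' returns the ROC polygon from (0, 0) to (1, 1) together with the
#' trapezoidal area under it — equivalently, the Mann-Whitney probability that
#' a random positive outscores a random negative, with ties counting one half.
#'
#' @param scores Numeric decision scores, larger meaning more positive.
#' @param truth Binary ground truth (logical, or coercible factor with
#'   `positive` naming the positive class).
#' @param positive Positive class label when `truth` is not logical.
#' @return A list with `roc_points` (tibble of fpr, tpr) and `auc`.
#' @export
roc_curve_auc <- function(scores, truth, positive = NULL) {
  if (!is.logical(truth)) {
    if (is.null(positive)) stop("positive class must be named for non-logical truth")
    truth <- truth == positive
  }
  stopifnot(length(scores) == length(truth), length(scores) > 0)
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0) stop("ROC needs at least one positive and one negative")
  if (max(scores) == min(scores)) {
    warning("constant scores: degenerate single-point ROC, AUC = 0.5")
    return(list(roc_points = tibble::tibble(fpr = c(0, 1), tpr = c(0, 1)),
                auc = 0.5))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # collapse tied thresholds
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc_points = tibble::tibble(fpr = fpr, tpr = tpr), auc = auc)
}

#' Sensitivity, specificity, and accuracy
#'
#' Binary: sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/n, each in percent. Multi-class: per-class one-vs-rest sensitivity
#' and specificity, macro-averaged (classes absent from the truth are excluded
#' with a warning); accuracy is the overall fraction correct.
#'
#' @param truth,predicted Aligned label vectors.
#' @param positive_class Positive label for the binary case; `NULL` triggers
#'   the macro-averaged multi-class path.
#' @return Named numeric vector: `sensitivity`, `specificity`, `accuracy` (%).
#' @export
compute_metrics <- function(truth, predicted, positive_class = NULL) {
  stopifnot(length(truth) == length(predicted), length(truth) > 0)
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (!is.null(positive_class)) {
    tp <- sum(truth == positive_class & predicted == positive_class)
    fn <- sum(truth == positive_class & predicted != positive_class)
    tn <- sum(truth != positive_class & predicted != positive_class)
    fp <- sum(truth != positive_class & predicted == positive_class)
    return(c(sensitivity = 100 * tp / (tp + fn),
             specificity = 100 * tn / (tn + fp),
             accuracy = 100 * (tp + tn) / length(truth)))
  }
  classes <- unique(c(truth, predicted))
  present <- classes[classes %in% truth]
  absent <- setdiff(classes, present)
  if (length(absent)) {
    warning("classes absent from truth excluded from macro average: ",
            paste(absent, collapse = ", "))
  }
  per <- vapply(present, function(cl) {
    m <- compute_metrics(truth, predicted, positive_class = cl)
    m[c("sensitivity", "specificity")]
  }, numeric(2))
  c(sensitivity = mean(per["sensitivity", ]),
    specificity = mean(per["specificity", ]),
    accuracy = 100 * mean(truth == predicted))
}

# Fit one SVM fold and return out-of-fold predictions and scores.
svm_fold <- function(train, test, features, classes, config) {
  w <- table(train$.class)
  w <- setNames(as.numeric(sum(w) / (length(w) * w)), names(w))
  x_tr <- as.matrix(train[, features, drop = FALSE])
  x_te <- as.matrix(test[, features, drop = FALSE])
  multi <- length(classes) > 2
  fit <- e1071::svm(x_tr, train$.class, kernel = config$svm_kernel,
                    cost = config$svm_cost, class.weights = w,
                    scale = apply(x_tr, 2, sd) > 0)
  if (multi) {
    pr <- predict(fit, x_te, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # per-class scores from the one-vs-one machine: pairwise vote counts
    # plus a bounded margin tie-breaker. Votes are piecewise in feature
    # space, so the middle class of an ordinal triplet can outscore both
    # neighbours — no single linear one-vs-rest scorer can do that — and
    # unlike Platt probability estimates this is deterministic (no non-R
    # RNG involved).
    votes <- matrix(0, nrow(x_te), length(classes),
                    dimnames = list(NULL, classes))
    frac <- votes
    for (j in seq_len(ncol(dv))) {
      pair <- strsplit(colnames(dv)[j], "/")[[1]]
      votes[, pair[1]] <- votes[, pair[1]] + (dv[, j] > 0)
      votes[, pair[2]] <- votes[, pair[2]] + (dv[, j] <= 0)
      frac[, pair[1]] <- frac[, pair[1]] + tanh(dv[, j])
      frac[, pair[2]] <- frac[, pair[2]] - tanh(dv[, j])
    }
    scores <- votes + frac / (2 * length(classes))
    list(pred = as.character(pr), scores = scores)
  } else {
    pr <- predict(fit, x_te, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    lv <- strsplit(colnames(dv)[1], "/")[[1]]
    # orient scores so larger favours the second class in `classes`
    sc <- if (lv[1] == classes[2]) dv[, 1] else -dv[, 1]
    list(pred = as.character(pr), scores = sc)
  }
}

#' Cross-validated SVM evaluation of one task
#'
#' Trains a support-vector machine per fold (standardization fitted on the
#' training folds only, class-balanced weights, linear kernel by default),
#' pools the out-of-fold predictions and continuous decision scores, and
#' computes sensitivity/specificity/accuracy plus ROC/AUC on the pooled
#' predictions. Multi-class tasks use one-vs-one voting for labels and
#' macro-averaged one-vs-rest AUC on class scores.
#'
#' @param cohort Feature table (one row per eye) with `label` and
#'   `subject_id` columns.
#' @param task A [task_spec()] or task id string.
#' @param features Character vector of feature columns to use.
#' @param folds Number of cross-validation folds (default 5; reduced with a
#'   warning when a class is smaller than the fold count).
#' @param seed Integer seed for the fold assignment.
#' @param config Parameter list from [octa_config()].
#' @return An object of class `classifier_report`.
#' @export
train_task <- function(cohort, task, features, folds = 5, seed = 1L,
                       config = octa_config()) {
  if (is.character(task)) task <- task_spec(task)
  if (!length(features)) stop("features must be nonempty")
  data <- task_cohort(cohort, task)
  if (nlevels(droplevels(data$.class)) < 2) {
    stop("single-class cohort for task ", task$task_id)
  }
  fold <- make_folds(data$.class, data$subject_id, k = folds, seed = seed,
                     group_by_subject = config$group_by_subject)
  k <- max(fold)
  classes <- task$classes
  multi <- length(classes) > 2
  pred <- character(nrow(data))
  scores <- if (multi) matrix(NA_real_, nrow(data), length(classes),
                              dimnames = list(NULL, classes))
            else numeric(nrow(data))
  for (f in seq_len(k)) {
    te <- fold == f
    res <- svm_fold(data[!te, , drop = FALSE], data[te, , drop = FALSE],
                    features, classes, config)
    pred[te] <- res$pred
    if (multi) scores[te, ] <- res$scores else scores[te] <- res$scores
  }
  met <- compute_metrics(data$.class, pred, positive_class = task$positive %|na|% NULL)
  if (multi) {
    per_class <- lapply(classes, function(cl)
      roc_curve_auc(scores[, cl], data$.class == cl))
    auc <- mean(vapply(per_class, `[[`, numeric(1), "auc"))
    roc_points <- dplyr::bind_rows(lapply(seq_along(classes), function(i)
      dplyr::mutate(per_class[[i]]$roc_points, class = classes[i])))
  } else {
    roc <- roc_curve_auc(scores, data$.class, positive = task$positive)
    auc <- roc$auc
    roc_points <- roc$roc_points
  }
  structure(list(
    task_id = task$task_id,
    feature_subset = features,
    fold_assignments = tibble::tibble(subject_id = data$subject_id,
                                      eye = data$eye, fold = fold),
    predictions = tibble::tibble(subject_id = data$subject_id,
                                 truth = as.character(data$.class),
                                 predicted = pred),
    scores = scores,
    sensitivity = unname(met["sensitivity"]),
    specificity = unname(met["specificity"]),
    accuracy = unname(met["accuracy"]),
    roc_points = roc_points,
    auc = auc,
    folds = k
  ), class = "classifier_report")
}

`%|na|%` <- function(x, y) if (length(x) == 1 && is.na(x)) y else x

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s (%d-fold CV, %d features)\n",
              x$task_id, x$folds, length(x$feature_subset)))
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%  AUC %.3f\n",
              x$sensitivity, x$specificity, x$accuracy, x$auc))
  invisible(x)
}

#' Assemble the hierarchical multi-task model
#'
#' Trains one full-data SVM per task on its optimal feature subset and wires
#' the routing: stage 1 separates control from disease; stage 2 runs only on
#' stage-1 "disease" outputs and separates DR from SCR; stages 3a/3b stage the
#' matching branch (NPDR 3-class, SCR binary).
#'
#' @param cohort Feature table with `label` and `subject_id` columns.
#' @param feature_sets Named list of retained feature vectors, one per task id.
#' @param config Parameter list from [octa_config()].
#' @return An object of class `hierarchical_octa_model`; see
#'   [predict.hierarchical_octa_model()].
#' @export
assemble_hierarchy <- function(cohort, feature_sets, config = octa_config()) {
  missing_tasks <- setdiff(octa_tasks(), names(feature_sets))
  if (length(missing_tasks)) {
    stop("missing stage model(s): ", paste(missing_tasks, collapse = ", "))
  }
  models <- lapply(octa_tasks(), function(tid) {
    task <- task_spec(tid)
    data <- task_cohort(cohort, task)
    feats <- feature_sets[[tid]]
    x <- as.matrix(data[, feats, drop = FALSE])
    w <- table(data$.class)
    w <- setNames(as.numeric(sum(w) / (length(w) * w)), names(w))
    fit <- e1071::svm(x, data$.class, kernel = config$svm_kernel,
                      cost = config$svm_cost, class.weights = w,
                      scale = apply(x, 2, sd) > 0)
    list(task = task, features = feats, fit = fit)
  })
  names(models) <- octa_tasks()
  structure(list(models = models), class = "hierarchical_octa_model")
}

#' Predict cohort labels through the hierarchy
#'
#' Routes each feature row through the staged classifiers: control vs.
#' disease, then DR vs. SCR for disease rows, then the matching severity
#' stager. Every row receives exactly one leaf label.
#'
#' @param object A [assemble_hierarchy()] model.
#' @param newdata Feature table (same columns as the training cohort).
#' @param ... Unused.
#' @return Tibble with columns `stage1`, `stage2`, `stage3`, and `leaf` (a
#'   cohort label).
#' @export
predict.hierarchical_octa_model <- function(object, newdata, ...) {
  stage_pred <- function(tid, rows) {
    m <- object$models[[tid]]
    x <- as.matrix(newdata[rows, m$features, drop = FALSE])
    as.character(predict(m$fit, x))
  }
  n <- nrow(newdata)
  s1 <- stage_pred("control_vs_disease", seq_len(n))
  s2 <- rep(NA_character_, n)
  s3 <- rep(NA_character_, n)
  leaf <- rep(NA_character_, n)
  leaf[s1 == "control"] <- "control"
  dis <- which(s1 == "disease")
  if (length(dis)) {
    s2[dis] <- stage_pred("dr_vs_scr", dis)
    dr <- dis[s2[dis] == "DR"]
    scr <- dis[s2[dis] == "SCR"]
    if (length(dr)) {
      s3[dr] <- stage_pred("npdr_staging", dr)
      leaf[dr] <- paste0(s3[dr], "_npdr")
    }
    if (length(scr)) {
      s3[scr] <- stage_pred("scr_staging", scr)
      leaf[scr] <- paste0(s3[scr], "_scr")
    }
  }
  tibble::tibble(stage1 = s1, stage2 = s2, stage3 = s3, leaf = leaf)
}
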