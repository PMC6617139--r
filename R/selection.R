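#' Univariate statistical profile of the features
#'
#' Per feature: Shapiro-Wilk normality within each task group; if every group
#' is compatible with normality, a t-test (2 groups) or one-way ANOVA (more),
#' otherwise a Wilcoxon rank-sum or Kruskal-Wallis test; p-values
#' Bonferroni-corrected for the number of features tested. A zero-variance
#' group forces the nonparametric path (noted). The Spearman correlation
#' matrix among the features is attached as attribute `"spearman"`.
#'
#' @param cohort Feature table with a `label` column.
#' @param task A [task_spec()] (or id) defining the groups; `NULL` compares
#'   the raw labels.
#' @param features Feature columns (default [octa_feature_names()]).
#' @param alpha Normality-gate level on the Shapiro-Wilk p (default 0.05).
#' @return A tibble: feature, test, p_value, p_adjusted, normal, note.
#' @export
univariate_profile <- function(cohort, task = NULL,
                               features = octa_feature_names(),
                               alpha = 0.05) {
  if (is.character(task)) task <- task_spec(task)
  data <- if (is.null(task)) {
    out <- cohort; out$.class <- factor(out$label); out
  } else task_cohort(cohort, task)
  groups <- split(seq_len(nrow(data)), data$.class)
  if (any(vapply(groups, length, numeric(1)) < 3)) {
    stop("each group needs at least 3 observations")
  }
  m <- length(features)
  rows <- lapply(features, function(f) {
    xs <- lapply(groups, function(i) data[[f]][i])
    zero_var <- any(vapply(xs, function(x) sd(x) == 0, logical(1)))
    normal <- !zero_var && all(vapply(xs, function(x)
      stats::shapiro.test(x)$p.value > alpha, logical(1)))
    note <- if (zero_var) "zero-variance group: nonparametric forced" else NA_character_
    if (normal) {
      if (length(xs) == 2) {
        p <- stats::t.test(xs[[1]], xs[[2]])$p.value
        test <- "t-test"
      } else {
        p <- summary(stats::aov(data[[f]] ~ data$.class))[[1]]$`Pr(>F)`[1]
        test <- "anova"
      }
    } else {
      if (length(xs) == 2) {
        p <- stats::wilcox.test(xs[[1]], xs[[2]], exact = FALSE)$p.value
        test <- "wilcoxon"
      } else {
        p <- stats::kruskal.test(data[[f]], data$.class)$p.value
        test <- "kruskal-wallis"
      }
    }
    tibble::tibble(feature = f, test = test, p_value = p,
                   p_adjusted = min(1, p * m), normal = normal, note = note)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "spearman") <- cor(as.matrix(data[, features]), method = "spearman")
  out
}

# Likelihood-ratio p of a one-predictor task model vs. the null model.
# Returns the p-value and a separation flag.
single_feature_lrt <- function(y, x) {
  multi <- nlevels(y) > 2
  sep <- FALSE
  if (multi) {
    fit <- nnet::multinom(y ~ x, trace = FALSE)
    null <- nnet::multinom(y ~ 1, trace = FALSE)
    stat <- null$deviance - fit$deviance
    df <- nlevels(y) - 1
  } else {
    fit <- withCallingHandlers(
      stats::glm(y ~ x, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    fp <- stats::fitted(fit)
    if (all(abs(fp - (as.integer(y) - 1)) < 1e-6)) sep <- TRUE
    stat <- fit$null.deviance - fit$deviance
    df <- 1
  }
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  if (sep) p <- min(p, .Machine$double.eps)
  list(p = p, separation = sep)
}

#' Univariate logistic screen
#'
#' Fits a one-predictor logistic model (binomial for two-class tasks,
#' multinomial for three-class staging) per feature and keeps those whose
#' likelihood-ratio p-value falls below `p_enter`. Complete separation keeps
#' the feature with p recorded below machine epsilon and a separation flag.
#'
#' @inheritParams univariate_profile
#' @param p_enter Screening threshold (default 0.15).
#' @return A tibble: feature, p_value, separation, keep.
#' @export
univariate_screen <- function(cohort, task, features = octa_feature_names(),
                              p_enter = 0.15) {
  if (is.character(task)) task <- task_spec(task)
  data <- task_cohort(cohort, task)
  y <- droplevels(data$.class)
  rows <- lapply(features, function(f) {
    r <- single_feature_lrt(y, data[[f]])
    tibble::tibble(feature = f, p_value = r$p, separation = r$separation,
                   keep = r$p < p_enter)
  })
  dplyr::bind_rows(rows)
}

# Multivariate task model and single-term-deletion LRT p-values.
multivariate_lrt <- function(y, x) {
  df <- as.data.frame(x)
  notes <- character(0)
  if (nlevels(y) > 2) {
    full <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 500)
    ps <- vapply(names(df), function(f) {
      rest <- setdiff(names(df), f)
      red <- if (length(rest)) {
        nnet::multinom(y ~ ., data = df[, rest, drop = FALSE],
                       trace = FALSE, maxit = 500)
      } else {
        nnet::multinom(y ~ 1, trace = FALSE)
      }
      stats::pchisq(red$deviance - full$deviance, df = nlevels(y) - 1,
                    lower.tail = FALSE)
    }, numeric(1))
  } else {
    full <- withCallingHandlers(
      stats::glm(y ~ ., data = df, family = stats::binomial(),
                 control = stats::glm.control(maxit = 100)),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (!full$converged) notes <- c(notes, "glm did not converge; maxit raised")
    d1 <- stats::drop1(full, test = "LRT")
    ps <- setNames(d1$`Pr(>Chi)`[-1], rownames(d1)[-1])
    # drop1 mangles non-syntactic names; map back positionally
    names(ps) <- names(df)
  }
  if (anyNA(ps)) {
    # aliased (collinear) predictors carry no information of their own
    notes <- c(notes, paste("aliased predictor(s):",
                            paste(names(ps)[is.na(ps)], collapse = ", ")))
    ps[is.na(ps)] <- 1
  }
  list(p = ps, notes = unique(notes))
}

#' Stepwise backward elimination of features
#'
#' Starts from the candidate set (normally the survivors of
#' [univariate_screen()]), fits the multivariate logistic model, and
#' repeatedly removes the predictor with the largest single-term-deletion
#' likelihood-ratio p-value while that p is at least `p_remove` (ties broken
#' by lower single-feature cross-validated accuracy — the worst predictor
#' goes). Each step logs the removed feature, its p-value, and the refitted
#' model's cross-validated SVM accuracy. The retained set is additionally
#' reported against the stricter `p_final`. If every candidate is eliminated,
#' the single best feature by cross-validated accuracy is returned with an
#' `all_eliminated` warning and flag.
#'
#' @inheritParams univariate_profile
#' @param candidates Feature names to start from.
#' @param p_remove Removal threshold on the multivariate p (default 0.10).
#' @param p_final Final reporting threshold (default 0.05).
#' @param folds,seed Cross-validation controls for the logged accuracies.
#' @param config Parameter list from [octa_config()].
#' @param accuracies Compute the per-feature single-feature accuracy table
#'   (default TRUE).
#' @return An object of class `elimination_trace`.
#' @export
backward_eliminate <- function(cohort, task, candidates,
                               p_remove = 0.10, p_final = 0.05,
                               folds = 5, seed = 1L, config = octa_config(),
                               accuracies = TRUE) {
  if (is.character(task)) task <- task_spec(task)
  data <- task_cohort(cohort, task)
  y <- droplevels(data$.class)
  if (!length(candidates)) stop("candidate set is empty")
  acc_cache <- new.env(parent = emptyenv())
  feat_acc <- function(f) {
    if (is.null(acc_cache[[f]])) {
      acc_cache[[f]] <- per_feature_accuracy(cohort, task, f, folds = folds,
                                             seed = seed, config = config)
    }
    acc_cache[[f]]
  }
  current <- candidates
  steps <- list()
  notes <- character(0)
  all_eliminated <- FALSE
  final_p <- NULL
  repeat {
    fit <- multivariate_lrt(y, data[, current, drop = FALSE])
    notes <- c(notes, fit$notes)
    final_p <- fit$p
    worst <- max(fit$p)
    if (worst < p_remove) break
    tied <- names(fit$p)[fit$p > worst - 1e-12]
    removed <- if (length(tied) > 1) {
      tied[which.min(vapply(tied, feat_acc, numeric(1)))]
    } else tied
    current <- setdiff(current, removed)
    if (!length(current)) {
      warning("backward elimination removed every candidate feature")
      all_eliminated <- TRUE
      best <- candidates[which.max(vapply(candidates, feat_acc, numeric(1)))]
      current <- best
      final_p <- setNames(NA_real_, best)
      steps[[length(steps) + 1]] <- tibble::tibble(
        step = length(steps) + 1, removed = removed,
        p_value = unname(fit$p[removed]), accuracy_after = NA_real_)
      break
    }
    rep_after <- train_task(cohort, task, current, folds = folds, seed = seed,
                            config = config)
    steps[[length(steps) + 1]] <- tibble::tibble(
      step = length(steps) + 1, removed = removed,
      p_value = unname(fit$p[removed]), accuracy_after = rep_after$accuracy)
  }
  per_acc <- if (accuracies) {
    tibble::tibble(feature = candidates,
                   accuracy = vapply(candidates, feat_acc, numeric(1)))
  } else NULL
  structure(list(
    task_id = task$task_id,
    screened_in = candidates,
    steps = if (length(steps)) dplyr::bind_rows(steps) else
      tibble::tibble(step = integer(), removed = character(),
                     p_value = numeric(), accuracy_after = numeric()),
    retained = current,
    retained_p = tibble::tibble(
      feature = names(final_p), p_value = unname(final_p),
      meets_p_final = !is.na(final_p) & final_p < p_final),
    per_feature_accuracy = per_acc,
    all_eliminated = all_eliminated,
    p_remove = p_remove, p_final = p_final,
    notes = unique(notes)
  ), class = "elimination_trace")
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf("<elimination_trace> %s: %d candidate(s) -> %d retained%s\n",
              x$task_id, length(x$screened_in), length(x$retained),
              if (x$all_eliminated) " (all eliminated; best single kept)" else ""))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Cross-validated single-feature accuracy
#'
#' Accuracy (%) of the task classifier trained on one feature alone, under
#' the same stratified subject-grouped cross-validation as [train_task()].
#' Populates the per-feature diagnostic-accuracy table.
#'
#' @inheritParams backward_eliminate
#' @param feature One feature column name.
#' @param classifier `"svm"` (default) or `"logistic"`.
#' @return Accuracy in percent.
#' @export
per_feature_accuracy <- function(cohort, task, feature, folds = 5, seed = 1L,
                                 config = octa_config(),
                                 classifier = c("svm", "logistic")) {
  classifier <- match.arg(classifier)
  if (is.character(task)) task <- task_spec(task)
  if (classifier == "svm") {
    return(train_task(cohort, task, feature, folds = folds, seed = seed,
                      config = config)$accuracy)
  }
  data <- task_cohort(cohort, task)
  y <- droplevels(data$.class)
  fold <- make_folds(y, data$subject_id, k = folds, seed = seed,
                     group_by_subject = config$group_by_subject)
  pred <- character(nrow(data))
  for (f in seq_len(max(fold))) {
    te <- fold == f
    dtr <- data.frame(y = y[!te], x = data[[feature]][!te])
    dte <- data.frame(x = data[[feature]][te])
    if (nlevels(y) > 2) {
      fit <- nnet::multinom(y ~ x, data = dtr, trace = FALSE)
      pred[te] <- as.character(predict(fit, dte))
    } else {
      fit <- suppressWarnings(stats::glm(y ~ x, data = dtr, family = stats::binomial()))
      pr <- predict(fit, dte, type = "response")
      pred[te] <- levels(y)[1 + (pr > 0.5)]
    }
  }
  100 * mean(pred == as.character(y))
}

#' Screen then eliminate: the full feature-selection chain for one task
#'
#' Convenience wrapper running [univariate_screen()] at `p_enter` and
#' [backward_eliminate()] on the survivors. When no feature passes the
#' screen, elimination starts from all features with a note.
#'
#' @inheritParams backward_eliminate
#' @param p_enter Screening threshold (default 0.15).
#' @return An `elimination_trace` with the screen table attached as
#'   attribute `"screen"`.
#' @export
select_features <- function(cohort, task, features = octa_feature_names(),
                            p_enter = 0.15, p_remove = 0.10, p_final = 0.05,
                            folds = 5, seed = 1L, config = octa_config()) {
  if (is.character(task)) task <- task_spec(task)
  scr <- univariate_screen(cohort, task, features, p_enter = p_enter)
  candidates <- scr$feature[scr$keep]
  if (!length(candidates)) {
    warning("no feature passed the univariate screen; eliminating from all features")
    candidates <- features
  }
  tr <- backward_eliminate(cohort, task, candidates, p_remove = p_remove,
                           p_final = p_final, folds = folds, seed = seed,
                           config = config)
  attr(tr, "screen") <- scr
  tr
}
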