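#' Run the optimal-feature-identification and multi-task-classification chain
#'
#' For each task: univariate screen, backward elimination, and cross-validated
#' SVM training on the retained feature set; then the hierarchical composite
#' model is assembled from the per-task optima. Tasks whose cohort is empty
#' are skipped with a warning.
#'
#' @param cohort Feature table (one row per eye) with `subject_id`, `eye`,
#'   `label`, and the 13 feature columns.
#' @param tasks Task ids to run (default all four).
#' @param config Parameter list from [octa_config()].
#' @param seed Integer seed for fold assignment.
#' @return An object of class `octa_pipeline_result`: per-task
#'   `elimination_trace`s and `classifier_report`s, the hierarchical model,
#'   and tidy summary tables (`feature_accuracy` — the per-feature
#'   diagnostic-accuracy table — and `task_metrics`).
#' @export
run_octa_pipeline <- function(cohort, tasks = octa_tasks(),
                              config = octa_config(), seed = 1L) {
  traces <- list(); reports <- list()
  for (tid in tasks) {
    task <- task_spec(tid)
    if (!any(cohort$label %in% names(task$grouping))) {
      warning("task ", tid, " has an empty cohort; skipped")
      next
    }
    tr <- select_features(cohort, task, p_enter = config$p_enter,
                          p_remove = config$p_remove, p_final = config$p_final,
                          folds = config$folds, seed = seed, config = config)
    rep <- train_task(cohort, task, tr$retained, folds = config$folds,
                      seed = seed, config = config)
    traces[[tid]] <- tr
    reports[[tid]] <- rep
  }
  hier <- if (setequal(names(reports), octa_tasks())) {
    assemble_hierarchy(cohort, lapply(traces, `[[`, "retained"), config)
  }
  feature_accuracy <- purrr::map_dfr(names(traces), function(tid) {
    pa <- traces[[tid]]$per_feature_accuracy
    if (is.null(pa)) return(NULL)
    dplyr::mutate(pa, task_id = tid, .before = 1)
  })
  task_metrics <- purrr::map_dfr(reports, glance)
  structure(list(
    traces = traces, reports = reports, hierarchy = hier,
    feature_accuracy = feature_accuracy, task_metrics = task_metrics,
    config = config, seed = seed
  ), class = "octa_pipeline_result")
}

#' @export
print.octa_pipeline_result <- function(x, ...) {
  cat("<octa_pipeline_result>\n")
  print(x$task_metrics)
  invisible(x)
}

#' Per-feature accuracy table in wide layout
#'
#' The cross-validated single-feature diagnostic accuracies, features as rows
#' and tasks as columns, mirroring the per-feature accuracy table of the
#' elimination audit.
#'
#' @param result An `octa_pipeline_result`.
#' @return A tibble, one row per feature.
#' @export
feature_accuracy_table <- function(result) {
  stopifnot(inherits(result, "octa_pipeline_result"))
  tidyr::pivot_wider(result$feature_accuracy, names_from = "task_id",
                     values_from = "accuracy")
}

#' Write a feature table to CSV
#'
#' Column layout: subject_id, eye, label, then the 13 feature columns.
#'
#' @param cohort Feature table from [extract_cohort_features()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(cohort, path) {
  cols <- c("subject_id", "eye", "label", octa_feature_names())
  utils::write.csv(cohort[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV written by [write_features_csv()].
#' @return A tibble.
#' @export
read_features_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Hash a configuration list
#'
#' Stable hash of a resolved configuration, used to stamp reports so they can
#' be traced back to the exact parameter set that produced them.
#'
#' @param config Parameter list from [octa_config()].
#' @return A character hash.
#' @export
digest_config <- function(config) {
  rlang::hash(config[order(names(config))])
}
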