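#' Classification task definitions
#'
#' The four hierarchical tasks: control vs. disease, inter-disease (DR vs.
#' SCR), NPDR severity staging (3-class), and SCR severity staging. Each task
#' maps cohort labels to task classes; rows with labels outside the map are
#' excluded from the task.
#'
#' @param task_id One of `"control_vs_disease"`, `"dr_vs_scr"`,
#'   `"npdr_staging"`, `"scr_staging"`.
#' @return An object of class `task_spec` with fields `task_id`, `grouping`
#'   (named character: label -> class), `classes`, and `positive` (the class
#'   treated as positive for binary metrics).
#' @export
task_spec <- function(task_id = c("control_vs_disease", "dr_vs_scr",
                                  "npdr_staging", "scr_staging")) {
  task_id <- match.arg(task_id)
  grouping <- switch(task_id,
    control_vs_disease = c(control = "control", mild_npdr = "disease",
                           moderate_npdr = "disease", severe_npdr = "disease",
                           mild_scr = "disease", severe_scr = "disease"),
    dr_vs_scr = c(mild_npdr = "DR", moderate_npdr = "DR", severe_npdr = "DR",
                  mild_scr = "SCR", severe_scr = "SCR"),
    npdr_staging = c(mild_npdr = "mild", moderate_npdr = "moderate",
                     severe_npdr = "severe"),
    scr_staging = c(mild_scr = "mild", severe_scr = "severe")
  )
  classes <- unique(unname(grouping))
  positive <- switch(task_id,
    control_vs_disease = "disease",
    dr_vs_scr = "SCR",
    npdr_staging = NA_character_,  # 3-class: macro-averaged metrics
    scr_staging = "severe"
  )
  structure(list(task_id = task_id, grouping = grouping, classes = classes,
                 positive = positive),
            class = "task_spec")
}

#' All task identifiers
#' @return Character vector of the four task ids in hierarchy order.
#' @export
octa_tasks <- function() {
  c("control_vs_disease", "dr_vs_scr", "npdr_staging", "scr_staging")
}

# Restrict a cohort table to a task: returns data with a `.class` factor.
task_cohort <- function(cohort, task) {
  stopifnot(inherits(task, "task_spec"))
  keep <- cohort$label %in% names(task$grouping)
  out <- cohort[keep, , drop = FALSE]
  if (!nrow(out)) stop("no cohort rows match task ", task$task_id)
  out$.class <- factor(unname(task$grouping[out$label]), levels = task$classes)
  out
}

# Stratified k-fold assignment grouped by subject: all rows of one subject
# fall in the same fold; subjects are dealt round-robin within class.
make_folds <- function(classes, subjects, k = 5, seed = 1L,
                       group_by_subject = TRUE) {
  if (!group_by_subject) subjects <- as.character(seq_along(classes))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  subj_class <- tapply(as.character(classes), subjects, function(x)
    names(sort(table(x), decreasing = TRUE))[1])
  min_per_class <- min(table(unlist(subj_class)))
  if (min_per_class < k) {
    k <- max(2L, min_per_class)
    warning(sprintf("a class has fewer members than folds; reducing to %d folds", k))
  }
  fold_of_subject <- integer(0)
  for (cl in unique(unlist(subj_class))) {
    subj <- sample(names(subj_class)[subj_class == cl])
    f <- rep(seq_len(k), length.out = length(subj))
    fold_of_subject[subj] <- f
  }
  unname(fold_of_subject[as.character(subjects)])
}
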