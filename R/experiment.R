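# End-to-end experiment driver: generate (or accept) cohorts, run every
# (strategy x augmentation method) cell, and write a result table. The
# numbered scripts under analysis/ are thin wrappers around this.

#' Configuration of a full experiment
#'
#' @param train_spec [cohort_spec()] for the training/validation cohort.
#' @param test_spec [cohort_spec()] for the independent test cohort (must
#'   use a different seed so subjects are distinct).
#' @param mc A [model_config()].
#' @param tc A [train_config()].
#' @param methods Named list of augmentation configurations; `NULL` entries
#'   mean no augmentation (baseline). Names become the method column.
#' @param strategies Subset of `"train100"`, `"holdout"`, `"cv_best"`,
#'   `"cv_mean"`.
#' @param seed Master seed echoed into per-cell seeds.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(train_spec = cohort_spec(seed = 101L),
                              test_spec = cohort_spec(n_subjects_per_class = 20L,
                                                      seed = 202L),
                              mc = model_config(),
                              tc = train_config(max_epochs = 30L, patience = 8L),
                              methods = list(baseline = NULL,
                                             CM = aug_config("CM"),
                                             `CM+SA` = list(aug_config("CM"),
                                                            aug_config("SA"))),
                              strategies = c("train100", "holdout",
                                             "cv_best", "cv_mean"),
                              seed = 1L) {
  strategies <- match.arg(strategies,
                          c("train100", "holdout", "cv_best", "cv_mean"),
                          several.ok = TRUE)
  structure(list(train_spec = train_spec, test_spec = test_spec, mc = mc,
                 tc = tc, methods = methods, strategies = strategies,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

run_cell <- function(strategy, train_ds, test_ds, mc, tc, aug) {
  switch(strategy,
         train100 = strategy_train100(train_ds, test_ds, mc, tc, aug),
         holdout = strategy_holdout(train_ds, test_ds, mc, tc, aug),
         cv_best = strategy_cv(train_ds, test_ds, "best", mc = mc, tc = tc,
                               aug = aug),
         cv_mean = strategy_cv(train_ds, test_ds, "mean", mc = mc, tc = tc,
                               aug = aug),
         stop("unknown strategy: ", strategy))
}

#' Run all (strategy x method) cells of an experiment
#'
#' Generates the two cohorts, standardizes them once, executes every cell,
#' and writes `results.tsv` plus a stage-level log into `run_dir`. A failed
#' cell is recorded in the log and the run continues.
#'
#' @param config An [experiment_config()].
#' @param run_dir Output directory.
#' @return List: `results` (list of `ddk_eval_result`), `report` (data
#'   frame), invisibly.
#' @export
run_experiment <- function(config, run_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(run_dir, "run.log")
  log_line <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ..., "\n",
                                file = log_path, append = TRUE)
  log_line("generate: train seed", config$train_spec$seed,
           "test seed", config$test_spec$seed)
  train_ds <- prepare_dataset(generate_cohort(config$train_spec))
  test_ds <- prepare_dataset(generate_cohort(config$test_spec))
  # test subjects get a distinct id prefix so disjointness is structural
  test_ds$meta$subject_id <- paste0("T-", test_ds$meta$subject_id)
  results <- list()
  cell <- 0L
  for (strategy in config$strategies) {
    for (mname in names(config$methods)) {
      cell <- cell + 1L
      tc <- config$tc
      tc$seed <- derive_seed(config$seed, cell)
      log_line("cell", cell, ":", strategy, "/", mname, "seed", tc$seed)
      res <- tryCatch(
        run_cell(strategy, train_ds, test_ds, config$mc, tc,
                 config$methods[[mname]]),
        error = function(e) {
          log_line("cell", cell, "FAILED:", conditionMessage(e))
          NULL
        })
      if (!is.null(res)) {
        res$method <- mname
        results[[paste(strategy, mname, sep = "/")]] <- res
      }
    }
  }
  report <- render_report(results)
  write_report(report, file.path(run_dir, "results.tsv"))
  log_line("done:", length(results), "of", cell, "cells")
  invisible(list(results = results, report = report))
}
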