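# Training and the four evaluation strategies: train-100%, holdout 70/30,
# and five-fold subject-independent cross-validation with best-model or
# mean-model selection. All splits are at subject level; augmentation is
# applied to training partitions only, and every strategy records its
# partitions so subject leakage can be asserted.

#' Training hyperparameters
#'
#' All values are tunable; none has a canonical published value for this
#' task. Defaults: Adam, learning rate 1e-3, batch 64, at most 100 epochs,
#' early-stopping patience 10 (only active when a validation set exists).
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum training epochs (> 0).
#' @param patience Early-stop patience in epochs (< `max_epochs`).
#' @param seed Seed controlling weight init and batch shuffling.
#' @return A `train_config` object.
#' @export
train_config <- function(lr = 1e-3, batch_size = 64L, max_epochs = 100L,
                         patience = 10L, seed = 1L) {
  tc <- list(lr = lr, batch_size = as.integer(batch_size),
             max_epochs = as.integer(max_epochs),
             patience = as.integer(patience), seed = as.integer(seed))
  if (tc$max_epochs < 1) stop("max_epochs must be positive")
  if (tc$batch_size < 1) stop("batch_size must be positive")
  if (tc$patience >= tc$max_epochs) stop("patience must be < max_epochs")
  class(tc) <- "train_config"
  tc
}

#' Standardize a cohort into a model-ready dataset
#'
#' Runs the full frontend (normalize, mono, 16 kHz, 160 ms segmentation,
#' 80x41 log-mel) once, keeping the segment waveforms for waveform-level
#' augmentation.
#' @param cohort A `ddk_cohort`.
#' @return A `ddk_dataset`: `segments` (2560 x n), `spec` (80 x 41 x n),
#'   `meta` (per-segment provenance incl. `subject_id`, `label`).
#' @export
prepare_dataset <- function(cohort) {
  segs <- preprocess_cohort(cohort)
  ms <- batch_melspec(segs)
  structure(list(segments = segs$samples, spec = ms$spec, meta = segs$meta),
            class = "ddk_dataset")
}

#' Restrict a dataset to a set of subjects
#' @param dataset A `ddk_dataset`.
#' @param subject_ids Subjects to keep.
#' @return The restricted `ddk_dataset`.
#' @export
subset_dataset <- function(dataset, subject_ids) {
  keep <- dataset$meta$subject_id %in% subject_ids
  structure(list(
    segments = if (is.null(dataset$segments)) NULL
               else dataset$segments[, keep, drop = FALSE],
    spec = dataset$spec[, , keep, drop = FALSE],
    meta = dataset$meta[keep, , drop = FALSE]),
    class = "ddk_dataset")
}

#' Unique subjects (with labels) of a dataset
#' @param dataset A `ddk_dataset`.
#' @return Data frame `subject_id`, `label`, one row per subject.
#' @export
dataset_subjects <- function(dataset) {
  df <- unique(dataset$meta[, c("subject_id", "label")])
  rownames(df) <- NULL
  df
}

assert_subject_disjoint <- function(a, b, what) {
  overlap <- intersect(a, b)
  if (length(overlap))
    stop("subject leakage between ", what, ": ",
         paste(overlap, collapse = ", "))
  invisible(TRUE)
}

#' Subject-independent stratified k-fold assignment
#'
#' Each subject lands in exactly one fold; per-fold class counts differ from
#' perfect balance by at most one.
#' @param subjects Data frame with columns `subject_id`, `label` (one row
#'   per subject), or a `ddk_dataset`.
#' @param k Number of folds.
#' @param seed Assignment seed.
#' @return Data frame `subject_id`, `label`, `fold` (1..k).
#' @export
make_folds <- function(subjects, k = 5L, seed = 1L) {
  if (inherits(subjects, "ddk_dataset")) subjects <- dataset_subjects(subjects)
  subjects <- unique(subjects[, c("subject_id", "label")])
  counts <- table(subjects$label)
  if (any(counts < k))
    stop("need at least k = ", k, " subjects per class; got ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  with_seed(seed, {
    parts <- lapply(split(subjects, subjects$label), function(df) {
      df <- df[sample.int(nrow(df)), , drop = FALSE]
      df$fold <- rep_len(seq_len(k), nrow(df))
      df
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })
}

dataset_xy <- function(ds) {
  list(x = ds$spec, y = as.integer(ds$meta$label == "PD"))
}

zero_like_params <- function(params) {
  rapply(params, function(p) p * 0, how = "replace")
}

subject_accuracy <- function(probs_pd, meta) {
  agg <- aggregate_to_subject(probs_pd, meta$subject_id)
  truth <- meta$label[match(agg$subject_id, meta$subject_id)]
  mean((agg$decision == "PD") == (truth == "PD"))
}

#' Train the CNN on a dataset
#'
#' Mini-batch Adam on softmax cross-entropy. With a validation set, the
#' weights of the epoch with the best subject-level validation accuracy are
#' returned and training stops early after `patience` epochs without
#' improvement; without one, the final-epoch weights are returned. Fully
#' deterministic given `tc$seed`.
#'
#' @param train_ds Training `ddk_dataset` (possibly augmented).
#' @param val_ds Optional validation `ddk_dataset` (never augmented).
#' @param mc A [model_config()].
#' @param tc A [train_config()].
#' @return List: `model` (`ddk_cnn`), `history` (per-epoch data frame),
#'   `best_epoch`.
#' @export
train_model <- function(train_ds, val_ds = NULL, mc = model_config(),
                        tc = train_config()) {
  n <- dim(train_ds$spec)[3]
  if (n == 0) stop("empty training set")
  xy <- dataset_xy(train_ds)
  model <- build_model(mc, seed = tc$seed)
  adam <- list(m = zero_like_params(model$params),
               v = zero_like_params(model$params), t = 0)
  best <- list(acc = -Inf, params = model$params, epoch = 0L)
  hist <- vector("list", tc$max_epochs)
  with_seed(derive_seed(tc$seed, 977L), {
    since_best <- 0L
    for (ep in seq_len(tc$max_epochs)) {
      perm <- sample.int(n)
      res <- cpp_cnn_train_epoch(model$params, adam, xy$x, xy$y, perm,
                                 tc$batch_size, tc$lr)
      model$params <- res$params
      adam <- res$adam
      val_acc <- NA_real_
      if (!is.null(val_ds)) {
        probs <- predict_proba(model, val_ds$spec)[, "PD"]
        val_acc <- subject_accuracy(probs, val_ds$meta)
        if (val_acc > best$acc) {
          best <- list(acc = val_acc, params = model$params, epoch = ep)
          since_best <- 0L
        } else {
          since_best <- since_best + 1L
        }
      }
      hist[[ep]] <- data.frame(epoch = ep, train_loss = res$loss,
                               train_acc = res$acc, val_acc = val_acc)
      if (!is.null(val_ds) && since_best >= tc$patience) break
    }
  })
  if (!is.null(val_ds)) {
    model$params <- best$params
    best_epoch <- best$epoch
  } else {
    best_epoch <- length(Filter(Negate(is.null), hist))
  }
  list(model = model, history = do.call(rbind, hist), best_epoch = best_epoch)
}

#' Evaluate a model on a dataset at subject level
#'
#' Segment PD-probabilities are averaged per subject; a subject is called PD
#' iff the mean probability is >= 0.5.
#' @param model A `ddk_cnn`.
#' @param ds A `ddk_dataset`.
#' @return List: `subjects` (per-subject truth, probability, decision),
#'   `cm` (confusion matrix), `metrics` (accuracy, sensitivity, specificity,
#'   f1).
#' @export
evaluate_model <- function(model, ds) {
  probs <- predict_proba(model, ds$spec)[, "PD"]
  agg <- aggregate_to_subject(probs, ds$meta$subject_id)
  agg$truth <- ds$meta$label[match(agg$subject_id, ds$meta$subject_id)]
  cm <- confusion_matrix(agg$truth, agg$decision)
  list(subjects = agg, cm = cm, metrics = confusion_to_metrics(cm))
}

maybe_augment <- function(ds, aug, seed) {
  if (is.null(aug)) {
    ds$meta$augmented <- FALSE
    ds$meta$source_subject <- ds$meta$subject_id
    return(ds)
  }
  expand_training_set(ds, aug, seed = seed)
}

eval_result <- function(strategy, method, test_eval = NULL, fold_metrics = NULL,
                        cv_accuracy = NULL, selected_fold = NULL,
                        partitions = NULL, aug_sources = NULL) {
  structure(list(
    strategy = strategy, method = method,
    metrics = if (!is.null(test_eval)) test_eval$metrics else NULL,
    cm = if (!is.null(test_eval)) test_eval$cm else NULL,
    subjects = if (!is.null(test_eval)) test_eval$subjects else NULL,
    fold_metrics = fold_metrics,
    fold_summary = if (!is.null(fold_metrics)) summarize_folds(fold_metrics) else NULL,
    cv_accuracy = cv_accuracy, selected_fold = selected_fold,
    partitions = partitions, aug_sources = aug_sources),
    class = "ddk_eval_result")
}

method_id <- function(aug) {
  if (is.null(aug)) return("baseline")
  if (inherits(aug, "aug_config")) aug <- list(aug)
  paste(vapply(aug, `[[`, character(1), "technique"), collapse = "+")
}

#' Train-100% strategy
#'
#' Trains on the entire training cohort for the full epoch budget (no
#' validation signal exists in this strategy) and evaluates once on the
#' independent test cohort.
#' @param train_ds,test_ds Prepared `ddk_dataset`s with disjoint subjects.
#' @param mc,tc Model and training configuration.
#' @param aug Optional augmentation config(s) for the training set.
#' @return A `ddk_eval_result`.
#' @export
strategy_train100 <- function(train_ds, test_ds, mc = model_config(),
                              tc = train_config(), aug = NULL) {
  tr_subj <- dataset_subjects(train_ds)$subject_id
  te_subj <- dataset_subjects(test_ds)$subject_id
  assert_subject_disjoint(tr_subj, te_subj, "train and test cohorts")
  tr <- maybe_augment(train_ds, aug, seed = derive_seed(tc$seed, 11L))
  assert_subject_disjoint(unique(tr$meta$source_subject), te_subj,
                          "augmentation sources and test subjects")
  fit <- train_model(tr, val_ds = NULL, mc = mc, tc = tc)
  eval_result("train100", method_id(aug), evaluate_model(fit$model, test_ds),
              partitions = list(train = tr_subj, test = te_subj),
              aug_sources = unique(tr$meta$source_subject))
}

#' Holdout 70/30 strategy
#'
#' Stratified subject-level 70/30 split of the training cohort; the model of
#' the best-validation-accuracy epoch is evaluated on the independent test
#' cohort.
#' @inheritParams strategy_train100
#' @return A `ddk_eval_result`.
#' @export
strategy_holdout <- function(train_ds, test_ds, mc = model_config(),
                             tc = train_config(), aug = NULL) {
  subs <- dataset_subjects(train_ds)
  te_subj <- dataset_subjects(test_ds)$subject_id
  assert_subject_disjoint(subs$subject_id, te_subj, "train and test cohorts")
  split <- with_seed(derive_seed(tc$seed, 31L), {
    lapply(split(subs$subject_id, subs$label), function(ids) {
      ids <- ids[sample.int(length(ids))]
      n_tr <- round(0.7 * length(ids))
      list(train = ids[seq_len(n_tr)], val = ids[-seq_len(n_tr)])
    })
  })
  tr_subj <- unlist(lapply(split, `[[`, "train"), use.names = FALSE)
  va_subj <- unlist(lapply(split, `[[`, "val"), use.names = FALSE)
  assert_subject_disjoint(tr_subj, va_subj, "train and validation partitions")
  tr <- maybe_augment(subset_dataset(train_ds, tr_subj), aug,
                      seed = derive_seed(tc$seed, 12L))
  assert_subject_disjoint(unique(tr$meta$source_subject), c(va_subj, te_subj),
                          "augmentation sources and held-out subjects")
  fit <- train_model(tr, subset_dataset(train_ds, va_subj), mc = mc, tc = tc)
  eval_result("holdout", method_id(aug), evaluate_model(fit$model, test_ds),
              partitions = list(train = tr_subj, val = va_subj, test = te_subj),
              aug_sources = unique(tr$meta$source_subject))
}

#' Pick a fold by validation accuracy
#'
#' `"best"` picks the fold with the highest accuracy; `"mean"` the fold
#' whose accuracy is closest to the across-fold mean. Ties go to the lowest
#' fold index.
#' @param accs Numeric vector of per-fold validation accuracies.
#' @param selection `"best"` or `"mean"`.
#' @return Selected fold index.
#' @export
select_fold <- function(accs, selection = c("best", "mean")) {
  selection <- match.arg(selection)
  if (selection == "best") which.max(accs)
  else which.min(abs(accs - mean(accs)))
}

#' Cross-validation strategy with best-model or mean-model selection
#'
#' Subject-independent stratified k-fold CV on the training cohort. Each
#' fold's model is selected at its best validation epoch; the across-fold
#' validation metrics are summarized as mean and SD, and the pooled
#' subject-level decisions over all validation folds give `cv_accuracy`.
#' One fold model is then selected (`"best"` or `"mean"`) and, if a test
#' cohort is supplied, evaluated on it.
#'
#' @inheritParams strategy_train100
#' @param test_ds Optional independent test `ddk_dataset`.
#' @param selection Fold-model selection rule, `"best"` or `"mean"`.
#' @param k Number of folds.
#' @return A `ddk_eval_result` with per-fold metrics, `cv_accuracy`,
#'   `selected_fold`, and (when `test_ds` is given) test metrics.
#' @export
strategy_cv <- function(train_ds, test_ds = NULL, selection = c("best", "mean"),
                        k = 5L, mc = model_config(), tc = train_config(),
                        aug = NULL) {
  selection <- match.arg(selection)
  te_subj <- if (!is.null(test_ds)) dataset_subjects(test_ds)$subject_id else character(0)
  assert_subject_disjoint(dataset_subjects(train_ds)$subject_id, te_subj,
                          "train and test cohorts")
  folds <- make_folds(train_ds, k = k, seed = derive_seed(tc$seed, 41L))
  fold_fits <- vector("list", k)
  fold_rows <- vector("list", k)
  pooled <- vector("list", k)
  aug_sources <- character(0)
  partitions <- list(test = te_subj)
  for (f in seq_len(k)) {
    va_subj <- folds$subject_id[folds$fold == f]
    tr_subj <- folds$subject_id[folds$fold != f]
    assert_subject_disjoint(tr_subj, va_subj, sprintf("fold %d train/val", f))
    tc_f <- tc
    tc_f$seed <- derive_seed(tc$seed, 500L + f)
    tr <- maybe_augment(subset_dataset(train_ds, tr_subj), aug,
                        seed = derive_seed(tc$seed, 600L + f))
    assert_subject_disjoint(unique(tr$meta$source_subject), c(va_subj, te_subj),
                            sprintf("fold %d augmentation sources", f))
    fit <- train_model(tr, subset_dataset(train_ds, va_subj), mc = mc, tc = tc_f)
    ev <- evaluate_model(fit$model, subset_dataset(train_ds, va_subj))
    fold_fits[[f]] <- fit
    fold_rows[[f]] <- data.frame(fold = f, t(ev$metrics))
    pooled[[f]] <- ev$subjects
    aug_sources <- union(aug_sources, unique(tr$meta$source_subject))
    partitions[[paste0("fold", f)]] <- va_subj
  }
  fold_metrics <- do.call(rbind, fold_rows)
  pooled <- do.call(rbind, pooled)
  cv_accuracy <- mean((pooled$decision == "PD") == (pooled$truth == "PD"))
  sel <- select_fold(fold_metrics$accuracy, selection)
  test_eval <- if (!is.null(test_ds))
    evaluate_model(fold_fits[[sel]]$model, test_ds) else NULL
  eval_result(paste0("cv_", selection), method_id(aug), test_eval,
              fold_metrics = fold_metrics, cv_accuracy = cv_accuracy,
              selected_fold = sel, partitions = partitions,
              aug_sources = aug_sources)
}
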