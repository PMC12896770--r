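# Folds, training, model selection, leakage guards.

test_that("stratified subject folds are balanced, disjoint, and seeded", {
  subjects <- data.frame(
    subject_id = sprintf("S%03d", 1:100),
    label = rep(c("PD", "HC"), each = 50))
  f <- make_folds(subjects, k = 5, seed = 2)
  expect_equal(sort(unique(f$fold)), 1:5)
  per_fold <- table(f$fold, f$label)
  expect_true(all(per_fold == 10)) # 10 PD + 10 HC per fold
  expect_equal(sort(f$subject_id), sort(subjects$subject_id)) # each exactly once
  expect_identical(make_folds(subjects, k = 5, seed = 2), f)
  f3 <- make_folds(subjects, k = 5, seed = 3)
  expect_false(identical(f3$fold[match(f$subject_id, f3$subject_id)], f$fold))
  expect_error(make_folds(subjects[c(1:3, 51:53), ], k = 5), "at least k")
})

test_that("uneven classes stay within one subject of perfect balance", {
  subjects <- data.frame(subject_id = sprintf("S%02d", 1:23),
                         label = rep(c("PD", "HC"), c(11, 12)))
  f <- make_folds(subjects, k = 5, seed = 1)
  per_fold <- table(f$fold, f$label)
  expect_lte(max(per_fold) - min(per_fold), 1)
})

test_that("fold selection follows the best and closest-to-mean rules", {
  accs <- c(0.7, 0.8, 0.9)
  expect_equal(select_fold(accs, "best"), 3)
  expect_equal(select_fold(accs, "mean"), 2)
  # ties go to the lowest fold index
  expect_equal(select_fold(c(0.8, 0.8, 0.8), "best"), 1)
  expect_equal(select_fold(c(0.8, 0.8, 0.8), "mean"), 1)
  # max >= mean always holds for the best rule
  set.seed(1)
  for (i in 1:20) {
    a <- runif(5)
    expect_gte(a[select_fold(a, "best")], mean(a))
  }
})

test_that("training separates strongly separated synthetic classes", {
  ds <- tiny_separable_dataset()
  fit <- train_model(ds, NULL, model_config(),
                     train_config(max_epochs = 30L, patience = 5L, seed = 2L))
  expect_gte(utils::tail(fit$history$train_acc, 1), 0.95)
})

test_that("training is deterministic given seed and data", {
  ds <- tiny_separable_dataset()
  tc <- train_config(max_epochs = 3L, patience = 2L, seed = 8L)
  a <- train_model(ds, NULL, model_config(2), tc)
  b <- train_model(ds, NULL, model_config(2), tc)
  expect_identical(a$model$params, b$model$params)
  expect_identical(a$history, b$history)
  expect_error(train_model(make_tiny_dataset(0), NULL, model_config(2), tc),
               "empty training set")
})

test_that("holdout strategy splits subjects 70/30 per class without leakage", {
  ds <- tiny_separable_dataset()
  test_ds <- subset_dataset(ds, c("HC001", "HC002", "PD001", "PD002"))
  test_ds$meta$subject_id <- paste0("T-", test_ds$meta$subject_id)
  res <- strategy_holdout(ds, test_ds, model_config(2),
                          train_config(max_epochs = 4L, patience = 2L, seed = 1L))
  p <- res$partitions
  expect_equal(length(p$train), 2 * round(0.7 * 6)) # 6 subjects per class
  expect_equal(length(p$val), 12 - length(p$train))
  expect_length(intersect(p$train, p$val), 0)
  expect_length(intersect(p$train, p$test), 0)
  expect_length(intersect(p$val, p$test), 0)
  # deterministic re-run
  res2 <- strategy_holdout(ds, test_ds, model_config(2),
                           train_config(max_epochs = 4L, patience = 2L, seed = 1L))
  expect_identical(res$metrics, res2$metrics)
  expect_identical(res$partitions, res2$partitions)
})

test_that("overlapping train/test subjects raise a leakage error", {
  ds <- tiny_separable_dataset()
  expect_error(strategy_train100(ds, ds, model_config(2),
                                 train_config(max_epochs = 2L, patience = 1L)),
               "leakage")
})

test_that("cross-validation reports per-fold metrics and audits augmentation sources", {
  ds <- tiny_separable_dataset()
  res <- strategy_cv(ds, NULL, "mean", k = 3L, mc = model_config(2),
                     tc = train_config(max_epochs = 4L, patience = 2L, seed = 4L),
                     aug = aug_config("CM"))
  expect_equal(nrow(res$fold_metrics), 3)
  expect_true(all(c("accuracy", "sensitivity", "specificity", "f1") %in%
                    names(res$fold_metrics)))
  expect_equal(res$selected_fold,
               select_fold(res$fold_metrics$accuracy, "mean"))
  expect_gte(res$cv_accuracy, 0)
  # every fold's validation subjects appear exactly once
  val_subj <- unlist(res$partitions[grepl("^fold", names(res$partitions))])
  expect_setequal(val_subj, dataset_subjects(ds)$subject_id)
  expect_equal(anyDuplicated(val_subj), 0)
  # augmentation sources are training subjects only (never validation)
  expect_true(all(res$aug_sources %in% dataset_subjects(ds)$subject_id))
})

test_that("cutting-masking augmentation does not hurt CV accuracy on a hard task", {
  # moderate effects and few subjects make the task imperfect; the mean CV
  # accuracy over 5 seeds with CM must not fall more than 0.02 below baseline
  co <- generate_cohort(cohort_spec(
    n_subjects_per_class = 12L, recordings_per_subject = 1L, duration_s = 1.5,
    pd_rate_deficit = 0.6, pd_mod_depth_deficit = 0.15,
    pd_noise_excess = 0.005, seed = 303L))
  ds <- prepare_dataset(co)
  accs <- vapply(1:5, function(s) {
    tc <- train_config(max_epochs = 15L, patience = 5L, seed = 1000L + s)
    base <- strategy_cv(ds, NULL, "mean", k = 5L, tc = tc)$cv_accuracy
    cm <- strategy_cv(ds, NULL, "mean", k = 5L, tc = tc,
                      aug = aug_config("CM"))$cv_accuracy
    c(base, cm)
  }, numeric(2))
  expect_gte(mean(accs[2, ]) - mean(accs[1, ]), -0.02)
})

test_that("a tiny experiment run is reproducible byte-for-byte", {
  cfg <- experiment_config(
    train_spec = cohort_spec(n_subjects_per_class = 4L,
                             recordings_per_subject = 1L, duration_s = 1.5,
                             seed = 51L),
    test_spec = cohort_spec(n_subjects_per_class = 3L,
                            recordings_per_subject = 1L, duration_s = 1.5,
                            seed = 52L),
    mc = model_config(2),
    tc = train_config(max_epochs = 3L, patience = 2L),
    methods = list(baseline = NULL),
    strategies = "train100", seed = 9L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_experiment(cfg, d1)
  r2 <- run_experiment(cfg, d2)
  expect_equal(nrow(r1$report), 1)
  expect_identical(readLines(file.path(d1, "results.tsv")),
                   readLines(file.path(d2, "results.tsv")))
})
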