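# Confusion-matrix metrics at subject level, across-fold summaries, and
# result tables. PD is the positive class throughout.

#' Confusion matrix from truth and predicted labels
#' @param truth,pred Character vectors of `"PD"` / `"HC"` labels.
#' @return A `ddk_confusion`: list with counts `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_matrix <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  structure(list(
    TP = sum(truth == "PD" & pred == "PD"),
    FP = sum(truth == "HC" & pred == "PD"),
    TN = sum(truth == "HC" & pred == "HC"),
    FN = sum(truth == "PD" & pred == "HC")), class = "ddk_confusion")
}

#' Accuracy, sensitivity, specificity and F1 from a confusion matrix
#'
#' `accuracy = (TP+TN)/n`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`, `F1 = 2TP/(2TP+FP+FN)`.
#' @param cm A [confusion_matrix()] or list with `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric vector.
#' @export
confusion_to_metrics <- function(cm) {
  if (cm$TP + cm$FN == 0)
    stop("undefined metric: sensitivity (no positive subjects evaluated)")
  if (cm$TN + cm$FP == 0)
    stop("undefined metric: specificity (no negative subjects evaluated)")
  n <- cm$TP + cm$FP + cm$TN + cm$FN
  c(accuracy = (cm$TP + cm$TN) / n,
    sensitivity = cm$TP / (cm$TP + cm$FN),
    specificity = cm$TN / (cm$TN + cm$FP),
    f1 = 2 * cm$TP / (2 * cm$TP + cm$FP + cm$FN))
}

#' Integer confusion matrix implied by printed sensitivity/specificity
#'
#' Reconstructs counts on a known class layout (e.g. 20 PD / 20 HC) from
#' rounded sensitivity and specificity.
#' @param sensitivity,specificity Fractions in \[0, 1\].
#' @param n_pd,n_hc Class sizes.
#' @return A `ddk_confusion`.
#' @export
confusion_from_rates <- function(sensitivity, specificity, n_pd, n_hc) {
  tp <- round(sensitivity * n_pd)
  tn <- round(specificity * n_hc)
  structure(list(TP = tp, FP = n_hc - tn, TN = tn, FN = n_pd - tp),
            class = "ddk_confusion")
}

#' Check that a printed result row is internally consistent
#'
#' Rebuilds the integer confusion matrix from the printed sensitivity and
#' specificity on the given class layout, recomputes all four metrics, and
#' compares them (rounded half-up to 2 decimals) with the printed row.
#' @param accuracy,sensitivity,specificity,f1 Printed values (2 decimals).
#' @param n_pd,n_hc Class sizes of the evaluation set.
#' @return `TRUE` if consistent, `FALSE` otherwise.
#' @export
check_row_consistency <- function(accuracy, sensitivity, specificity, f1,
                                  n_pd = 20L, n_hc = 20L) {
  m <- confusion_to_metrics(confusion_from_rates(sensitivity, specificity,
                                                 n_pd, n_hc))
  all(round_half_up(m, 2) == c(accuracy, sensitivity, specificity, f1))
}

#' Aggregate segment probabilities to subject decisions
#'
#' A subject's PD probability is the mean of its segment PD probabilities;
#' the subject is called PD iff that mean is >= 0.5 (ties positive).
#' @param probs_pd Per-segment PD probabilities.
#' @param subject_ids Parallel vector of subject identifiers.
#' @return Data frame `subject_id`, `p_pd`, `decision` in first-appearance
#'   order.
#' @export
aggregate_to_subject <- function(probs_pd, subject_ids) {
  stopifnot(length(probs_pd) == length(subject_ids))
  if (length(probs_pd) == 0) stop("no segments to aggregate")
  ids <- unique(subject_ids)
  p <- vapply(ids, function(s) mean(probs_pd[subject_ids == s]), numeric(1))
  data.frame(subject_id = ids, p_pd = unname(p),
             decision = ifelse(p >= 0.5, "PD", "HC"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Across-fold mean and standard deviation
#'
#' Sample (n-1) standard deviation, the convention used for the
#' mean-plus-minus-SD entries of the result tables.
#' @param fold_metrics Data frame with one row per fold; non-numeric columns
#'   (e.g. `fold`) are ignored.
#' @return Data frame `metric`, `mean`, `sd`.
#' @export
summarize_folds <- function(fold_metrics) {
  num <- fold_metrics[, setdiff(names(fold_metrics), "fold"), drop = FALSE]
  num <- num[, vapply(num, is.numeric, logical(1)), drop = FALSE]
  if (nrow(num) < 2) stop("need at least 2 folds to summarize")
  data.frame(metric = names(num),
             mean = vapply(num, mean, numeric(1)),
             sd = vapply(num, sd, numeric(1)),
             row.names = NULL)
}

#' Result table over strategies and methods
#'
#' One row per (strategy, method) with metrics formatted to two decimals
#' (half-up), mirroring the layout of the study tables.
#' @param results List of `ddk_eval_result` objects.
#' @return Data frame with character metric columns; header-only if empty.
#' @export
render_report <- function(results) {
  fmt <- function(x) sprintf("%.2f", round_half_up(x, 2))
  rows <- lapply(results, function(r) {
    m <- if (!is.null(r$metrics)) {
      vapply(r$metrics, fmt, character(1))
    } else if (!is.null(r$fold_summary)) {
      s <- r$fold_summary
      stats_of <- function(name) {
        i <- match(name, s$metric)
        sprintf("%s±%s", fmt(s$mean[i]), fmt(s$sd[i]))
      }
      c(accuracy = stats_of("accuracy"), sensitivity = stats_of("sensitivity"),
        specificity = stats_of("specificity"), f1 = stats_of("f1"))
    } else {
      stop("eval result carries neither test metrics nor fold summaries")
    }
    data.frame(strategy = r$strategy, method = r$method,
               accuracy = m[["accuracy"]], sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]], f1 = m[["f1"]],
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(strategy = character(), method = character(),
                      accuracy = character(), sensitivity = character(),
                      specificity = character(), f1 = character()))
  do.call(rbind, rows)
}

#' Write a result table as tab-separated text
#' @param report Data frame from [render_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
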