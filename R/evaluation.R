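#' Patient-grouped random split plans
#'
#' Repeated holdout at the subject level: each plan assigns `n_train`
#' randomly chosen subjects to training and the rest to testing, so no
#' subject's ROIs ever straddle a split. Partitions are drawn
#' independently across repeats (the same partition may recur). Fully
#' reproducible from `seed`.
#'
#' @param subjects character vector of subject ids.
#' @param n_train number of training subjects (1 <= n_train < length);
#'   default 12.
#' @param n_repeats number of plans; default 100.
#' @param seed RNG seed.
#' @return List of plans, each with `repeat_index`, `train_subjects`,
#'   `test_subjects`, `seed`.
#' @export
make_splits <- function(subjects, n_train = 12L, n_repeats = 100L, seed = 1L) {
  subjects <- unique(as.character(subjects))
  n <- length(subjects)
  if (n_train < 1L || n_train >= n)
    stop("`n_train` must satisfy 1 <= n_train < number of subjects (", n, ")",
         call. = FALSE)
  set.seed(seed)
  lapply(seq_len(n_repeats), function(r) {
    tr <- sample(subjects, n_train)
    list(repeat_index = r, train_subjects = tr,
         test_subjects = setdiff(subjects, tr), seed = seed)
  })
}

#' ROC curve and AUC by threshold sweep
#'
#' Standard sweep over the distinct score values, a positive being a
#' score >= threshold. The trapezoidal AUC over the resulting step curve
#' equals the Mann-Whitney U statistic normalized by n_pos * n_neg (ties
#' credited 1/2).
#'
#' @param labels binary truth: logical, 0/1, or "E"/"NE" ("E" positive).
#' @param scores numeric scores, higher = more positive.
#' @return List with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(labels, scores) {
  if (is.character(labels) || is.factor(labels)) labels <- as.character(labels) == "E"
  y <- as.logical(labels)
  stopifnot(length(y) == length(scores), !anyNA(y), !anyNA(scores))
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(y & scores >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!y & scores >= t) / n_neg, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Youden-optimal operating point of an ROC curve
#'
#' Maximizes J = sensitivity + specificity - 1 over the sweep
#' thresholds; the first maximizer in decreasing-threshold order wins.
#'
#' @param roc result of [roc_curve()].
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden_j`.
#' @export
youden_optimal <- function(roc) {
  p <- roc$points
  j <- p$tpr - p$fpr
  k <- which.max(j)
  list(threshold = p$threshold[k], sensitivity = p$tpr[k],
       specificity = 1 - p$fpr[k], youden_j = j[k])
}

#' Patient-grouped cross-validated evaluation
#'
#' Per split plan: stepwise selection and logistic fitting on the
#' training subjects' ROIs only, prediction on the held-out subjects'
#' ROIs, accuracy at probability threshold 0.5, ROC/AUC over the test
#' probabilities, and the Youden-optimal sensitivity/specificity.
#' Aggregate metrics are arithmetic means over repeats; a repeat whose
#' test set contains one class has undefined AUC and is excluded from
#' the AUC/sensitivity/specificity means with a warning.
#'
#' @param table feature table with `subject_id`, `label` and feature
#'   columns.
#' @param plans list of split plans from [make_splits()].
#' @param p_enter,p_remove stepwise thresholds; defaults 0.05 / 0.15.
#' @param threshold classification threshold for accuracy; default 0.5.
#' @param ... further arguments to [stepwise_select()].
#' @return An object of class `eval_result`: `per_repeat` data.frame
#'   (accuracy, auc, optimal sensitivity/specificity, threshold, number
#'   of selected features), `aggregate` list of metric means,
#'   `n_repeats`.
#' @export
run_cv <- function(table, plans, p_enter = 0.05, p_remove = 0.15,
                   threshold = 0.5, ...) {
  subs <- unique(table$subject_id)
  rows <- lapply(plans, function(plan) {
    if (!setequal(c(plan$train_subjects, plan$test_subjects), subs))
      stop("split plan ", plan$repeat_index,
           " does not cover the table's subjects", call. = FALSE)
    tr <- table[table$subject_id %in% plan$train_subjects, , drop = FALSE]
    te <- table[table$subject_id %in% plan$test_subjects, , drop = FALSE]
    model <- suppressWarnings(
      stepwise_select(tr, p_enter = p_enter, p_remove = p_remove, ...))
    prob <- predict(model, te)
    y <- response_vector(te)
    acc <- mean((prob >= threshold) == (y == 1L))
    if (length(unique(y)) < 2L) {
      warning("repeat ", plan$repeat_index,
              ": single-class test set, AUC undefined for this repeat",
              call. = FALSE)
      auc <- sens <- spec <- opt_thr <- NA_real_
    } else {
      roc <- roc_curve(y, prob)
      opt <- youden_optimal(roc)
      auc <- roc$auc; sens <- opt$sensitivity; spec <- opt$specificity
      opt_thr <- opt$threshold
    }
    data.frame(repeat_index = plan$repeat_index, accuracy = acc, auc = auc,
               optimal_sensitivity = sens, optimal_specificity = spec,
               optimal_threshold = opt_thr,
               n_selected = length(model$selected_features))
  })
  per_repeat <- do.call(rbind, rows)
  aggregate <- list(
    accuracy = mean(per_repeat$accuracy),
    auc = mean(per_repeat$auc, na.rm = TRUE),
    optimal_sensitivity = mean(per_repeat$optimal_sensitivity, na.rm = TRUE),
    optimal_specificity = mean(per_repeat$optimal_specificity, na.rm = TRUE),
    n_auc_defined = sum(!is.na(per_repeat$auc)))
  structure(list(per_repeat = per_repeat, aggregate = aggregate,
                 n_repeats = nrow(per_repeat)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  a <- x$aggregate
  cat("<eval_result> ", x$n_repeats, " repeats\n",
      sprintf("  success rate %.2f%%  AUC %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              100 * a$accuracy, 100 * a$auc, 100 * a$optimal_sensitivity,
              100 * a$optimal_specificity), sep = "")
  invisible(x)
}

#' Serialize an evaluation result
#' @param result an `eval_result`.
#' @param json_path,csv_path output paths (either may be NULL).
#' @export
write_eval_result <- function(result, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(list(aggregate = result$aggregate,
                              n_repeats = result$n_repeats),
                         json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(csv_path))
    utils::write.csv(result$per_repeat, csv_path, row.names = FALSE)
  invisible(result)
}
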