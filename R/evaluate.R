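#' Confusion counts
#'
#' One-vs-rest tally: TP, FP, FN, TN plus the derived totals AIR = TP + FN
#' (samples truly of the positive class), DR = TP + FP (samples the model
#' retrieved as positive) and CDR = TP + TN (decisions consistent with
#' truth).
#'
#' @param tp,fp,fn,tn Non-negative counts (`tn` defaults to 0; it feeds CDR
#'   only and no metric).
#' @return Object of class `tcm_counts`.
#' @export
evaluation_counts <- function(tp, fp, fn, tn = 0) {
  vals <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 air = tp + fn, dr = tp + fp, cdr = tp + tn),
            class = "tcm_counts")
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP / DR`, `R = TP / AIR`, `F1 = 2PR / (P + R)` (the harmonic mean).
#' A zero denominator makes the metric undefined; it is reported as 0 with
#' the corresponding flag set, so cross-validation aggregation stays robust.
#' Values are stored raw in `[0, 1]`; the print method shows percentages
#' rounded to two decimals (display only).
#'
#' @param counts An [evaluation_counts()] object.
#' @return Object of class `tcm_metrics`: `precision`, `recall`, `f1`,
#'   logical flags `precision_defined`, `recall_defined`, `f1_defined`, and
#'   the input `counts`.
#' @examples
#' # retrieved 1172, of which 996 true positives -> P = 84.98%
#' m <- compute_metrics(evaluation_counts(tp = 996, fp = 176, fn = 894))
#' round(100 * m$precision, 2)
#' @export
compute_metrics <- function(counts) {
  if (!inherits(counts, "tcm_counts"))
    counts <- do.call(evaluation_counts, as.list(counts))
  p_def <- counts$dr > 0
  r_def <- counts$air > 0
  p <- if (p_def) counts$tp / counts$dr else 0
  r <- if (r_def) counts$tp / counts$air else 0
  f_def <- p_def && r_def && (p + r) > 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(precision = p, recall = r, f1 = f1,
                 precision_defined = p_def, recall_defined = r_def,
                 f1_defined = f_def, counts = counts),
            class = "tcm_metrics")
}

#' @export
print.tcm_metrics <- function(x, ...) {
  cat(sprintf("P = %.2f%%%s  R = %.2f%%%s  F1 = %.2f%%%s\n",
              100 * x$precision, if (x$precision_defined) "" else " (undef)",
              100 * x$recall, if (x$recall_defined) "" else " (undef)",
              100 * x$f1, if (x$f1_defined) "" else " (undef)"))
  invisible(x)
}

#' Metrics from retrieval-table totals
#'
#' Entry point for published count tables that report the retrieved total
#' DR and the relevant total AIR rather than FP/FN: reconstructs
#' `FP = DR - TP`, `FN = AIR - TP` and applies [compute_metrics()].
#'
#' @param tp True positives.
#' @param dr Retrieved total (TP + FP).
#' @param air Relevant total (TP + FN).
#' @return A `tcm_metrics` object.
#' @examples
#' round(100 * metrics_from_totals(tp = 639, dr = 921, air = 1890)$precision, 2)
#' @export
metrics_from_totals <- function(tp, dr, air) {
  if (dr < tp || air < tp)
    stop("DR and AIR must each be >= TP", call. = FALSE)
  compute_metrics(evaluation_counts(tp = tp, fp = dr - tp, fn = air - tp))
}

#' One-vs-rest confusion counts from aligned label vectors
#'
#' @param predictions Character vector of top-1 predicted labels (`NA` or
#'   `""` = no prediction, counted as a negative decision).
#' @param truths Character vector of true labels, same length.
#' @param positive_class The class treated as positive.
#' @return An [evaluation_counts()] object.
#' @export
confusion_counts <- function(predictions, truths, positive_class) {
  if (length(predictions) != length(truths))
    stop("predictions and truths must have equal length", call. = FALSE)
  pred_pos <- !is.na(predictions) & predictions == positive_class
  true_pos <- truths == positive_class
  evaluation_counts(tp = sum(pred_pos & true_pos),
                    fp = sum(pred_pos & !true_pos),
                    fn = sum(!pred_pos & true_pos),
                    tn = sum(!pred_pos & !true_pos))
}

#' Per-class and macro-averaged evaluation
#'
#' One-vs-rest metrics for every class present in the truth vector, plus
#' their unweighted (macro) means — invariant to class relabeling.
#'
#' @inheritParams confusion_counts
#' @return List with `per_class` (data frame: `class`, `tp`, `fp`, `fn`,
#'   `tn`, `precision`, `recall`, `f1`) and `macro` (named numeric:
#'   `precision`, `recall`, `f1`).
#' @export
evaluate_predictions <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    stop("predictions and truths must have equal length", call. = FALSE)
  classes <- sort(unique(truths), method = "radix")
  rows <- lapply(classes, function(cl) {
    cc <- confusion_counts(predictions, truths, cl)
    m <- compute_metrics(cc)
    data.frame(class = cl, tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
               precision = m$precision, recall = m$recall, f1 = m$f1,
               stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  list(per_class = per_class,
       macro = c(precision = mean(per_class$precision),
                 recall = mean(per_class$recall),
                 f1 = mean(per_class$f1)))
}

#' Assign cross-validation folds
#'
#' Seeded random partition into `k` folds whose sizes differ by at most one.
#' With `stratify = TRUE` (the default) records are shuffled within each
#' class and fold ids are dealt round-robin across the class-ordered
#' sequence, so per-class fold counts are also balanced within one.
#'
#' @param labels Character vector (one label per record).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; identical seeds give identical assignments.
#' @param stratify Balance folds per class (default `TRUE`).
#' @return Integer vector of fold ids in `1:k`, aligned with `labels`.
#' @export
make_folds <- function(labels, k = 10L, seed = 1L, stratify = TRUE) {
  n <- length(labels)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("need at least k records (", k, "), got ", n,
                  call. = FALSE)
  with_seed(seed, {
    ord <- if (stratify) order(labels, stats::runif(n)) else sample.int(n)
    folds <- integer(n)
    folds[ord] <- rep_len(seq_len(k), n)
    folds
  })
}

#' k-fold cross-validation of the rule-base classifier
#'
#' Splits the corpus into `k` folds ([make_folds()]), trains on `k - 1` folds
#' with [tcm_train()] and classifies the held-out fold with top-1
#' [tcm_classify()]; reports per-fold macro precision / recall / F1 and their
#' means.
#'
#' @param records List of [medical_record()] objects, length >= `k`.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param stratify Stratify folds by primary constitution (default `TRUE`).
#' @param ... Passed to [tcm_train()] (thresholds, shards, executor, ...).
#' @return Object of class `tcm_cv`: `folds` (data frame `fold`, `n_test`,
#'   `precision`, `recall`, `f1`) and `mean` (named numeric).
#' @export
cross_validate <- function(records, k = 10L, seed = 1L, stratify = TRUE,
                           ...) {
  labels <- vapply(records, `[[`, character(1), "primary_constitution")
  folds <- make_folds(labels, k = k, seed = seed, stratify = stratify)
  rows <- lapply(seq_len(k), function(f) {
    train_recs <- records[folds != f]
    test_recs <- records[folds == f]
    rb <- tcm_train(train_recs, ...)
    pred <- predict(rb, test_recs)
    ev <- evaluate_predictions(pred$predicted, pred$truth)
    data.frame(fold = f, n_test = length(test_recs),
               precision = ev$macro[["precision"]],
               recall = ev$macro[["recall"]],
               f1 = ev$macro[["f1"]])
  })
  folds_df <- do.call(rbind, rows)
  structure(list(folds = folds_df,
                 mean = c(precision = mean(folds_df$precision),
                          recall = mean(folds_df$recall),
                          f1 = mean(folds_df$f1))),
            class = "tcm_cv")
}

#' @export
print.tcm_cv <- function(x, ...) {
  cat("<tcm_cv> ", nrow(x$folds), "-fold cross-validation\n", sep = "")
  print.data.frame(x$folds, digits = 4)
  cat(sprintf("mean: P = %.2f%%  R = %.2f%%  F1 = %.2f%%\n",
              100 * x$mean[["precision"]], 100 * x$mean[["recall"]],
              100 * x$mean[["f1"]]))
  invisible(x)
}

#' Write a metrics report
#'
#' JSON (all fields) or a tab-separated table with the retrieval-count
#' columns `model`, `AIR`, `DR`, `TP`, `P`, `R`, `F1` (percentages to two
#' decimals).
#'
#' @param metrics A `tcm_metrics` object.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @param model Model name for the TSV row.
#' @export
write_metrics <- function(metrics, path, format = c("json", "tsv"),
                          model = "tcmrules") {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(precision = metrics$precision, recall = metrics$recall,
           f1 = metrics$f1,
           precision_defined = metrics$precision_defined,
           recall_defined = metrics$recall_defined,
           counts = unclass(metrics$counts)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(model = model, AIR = metrics$counts$air,
                     DR = metrics$counts$dr, TP = metrics$counts$tp,
                     P = sprintf("%.2f", 100 * metrics$precision),
                     R = sprintf("%.2f", 100 * metrics$recall),
                     F1 = sprintf("%.2f", 100 * metrics$f1),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
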