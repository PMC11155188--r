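#' Confusion counts at a probability threshold
#'
#' Malignant (label 1) is the positive class; a sample is called positive
#' when its predicted malignancy probability is greater than or equal to the
#' threshold.
#'
#' @param probs Predicted malignancy probabilities in `[0, 1]`.
#' @param labels Integer 0/1 labels.
#' @param threshold Decision threshold (default 0.5), boundary inclusive.
#' @return Named integer vector `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(probs, labels, threshold = 0.5) {
  if (length(probs) != length(labels)) {
    fh_stop("probs and labels differ in length", "fh_invalid_input")
  }
  pred <- probs >= threshold
  c(TP = sum(pred & labels == 1), FP = sum(pred & labels == 0),
    TN = sum(!pred & labels == 0), FN = sum(!pred & labels == 1))
}

#' Sensitivity, specificity, balanced accuracy and F1 from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `balanced accuracy = (sensitivity + specificity) / 2`,
#' `F1 = 2 TP / (2 TP + FP + FN)`. A ratio whose denominator is empty is
#' returned as `NA` (flagged undefined, never silently zero).
#'
#' @param TP,FP,TN,FN Non-negative counts.
#' @return List with `sensitivity`, `specificity`, `balanced_accuracy`, `f1`.
#' @export
#' @examples
#' m <- metrics_from_confusion(TP = 35, FP = 7, TN = 80, FN = 7)
#' round(m$balanced_accuracy, 3)
metrics_from_confusion <- function(TP, FP, TN, FN) {
  if (any(c(TP, FP, TN, FN) < 0)) fh_stop("counts must be non-negative", "fh_invalid_input")
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  f1 <- if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else NA_real_
  list(sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2, f1 = f1)
}

#' ROC and precision-recall curves with areas
#'
#' Threshold sweep over the unique scores: the ROC area is computed by the
#' trapezoidal rule (equivalently the pairwise concordance statistic), the PR
#' area by step-wise precision-at-recall summation.
#'
#' @param probs Predicted probabilities/scores.
#' @param labels Integer 0/1 labels; both classes must be present.
#' @return List with `roc` (data frame fpr/tpr/threshold), `auc_roc`, `pr`
#'   (data frame recall/precision/threshold), `auc_pr`.
#' @export
roc_pr_curves <- function(probs, labels) {
  P <- sum(labels == 1); Ng <- sum(labels == 0)
  if (P == 0 || Ng == 0) fh_stop("both classes must be present", "fh_undefined_curve")
  ord <- order(probs, decreasing = TRUE)
  s <- probs[ord]; y <- labels[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  keep <- c(which(diff(s) != 0), length(s))  # last index of each tied block
  tp <- tp[keep]; fp <- fp[keep]; thr <- s[keep]
  tpr <- c(0, tp / P); fpr <- c(0, fp / Ng)
  auc_roc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / P
  precision <- tp / (tp + fp)
  auc_pr <- sum(diff(c(0, recall)) * precision)
  list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = c(Inf, thr)),
       auc_roc = auc_roc,
       pr = data.frame(recall = recall, precision = precision, threshold = thr),
       auc_pr = auc_pr)
}

#' Decision-curve analysis (net benefit versus threshold probability)
#'
#' Net benefit at threshold `p_t` is `TP/n - FP/n * p_t / (1 - p_t)` with
#' positives called at predicted probability `>= p_t`. The treat-all and
#' treat-none reference policies are returned alongside.
#'
#' @param probs Predicted malignancy probabilities.
#' @param labels Integer 0/1 labels.
#' @param thresholds Threshold probabilities, all in (0, 1).
#' @return Data frame with `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`.
#' @export
decision_curve <- function(probs, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    fh_stop("thresholds must lie strictly in (0, 1)", "fh_invalid_input")
  }
  n <- length(labels)
  prev <- mean(labels == 1)
  nb <- vapply(thresholds, function(pt) {
    cm <- confusion(probs, labels, pt)
    cm[["TP"]] / n - cm[["FP"]] / n * pt / (1 - pt)
  }, numeric(1))
  data.frame(threshold = thresholds, net_benefit = nb,
             treat_all = prev - (1 - prev) * thresholds / (1 - thresholds),
             treat_none = 0)
}

#' Full evaluation report from predictions
#'
#' @param probs Predicted malignancy probabilities.
#' @param labels Integer 0/1 labels.
#' @param threshold Decision threshold for the confusion-based metrics.
#' @param dca_thresholds Thresholds for decision-curve analysis.
#' @return An object of class `fh_eval_report`: confusion counts, the four
#'   confusion metrics, ROC/PR curves and areas, and the decision curve.
#' @export
evaluate_predictions <- function(probs, labels, threshold = 0.5,
                                 dca_thresholds = seq(0.05, 0.95, by = 0.05)) {
  cm <- confusion(probs, labels, threshold)
  m <- metrics_from_confusion(cm[["TP"]], cm[["FP"]], cm[["TN"]], cm[["FN"]])
  curves <- if (length(unique(labels)) == 2) roc_pr_curves(probs, labels) else NULL
  structure(c(list(counts = cm, threshold = threshold, n = length(labels)),
              m,
              list(auc_roc = curves$auc_roc, auc_pr = curves$auc_pr,
                   roc = curves$roc, pr = curves$pr,
                   dca = decision_curve(probs, labels, dca_thresholds))),
            class = "fh_eval_report")
}

#' @export
print.fh_eval_report <- function(x, ...) {
  cat("Evaluation report (n =", x$n, ", threshold =", x$threshold, ")\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$counts[["TP"]],
              x$counts[["FP"]], x$counts[["TN"]], x$counts[["FN"]]))
  cat(sprintf("  balanced accuracy %.3f  sensitivity %.3f  specificity %.3f  F1 %.3f\n",
              x$balanced_accuracy, x$sensitivity, x$specificity, x$f1))
  if (!is.null(x$auc_roc)) {
    cat(sprintf("  AUC-ROC %.3f  AUC-PR %.3f\n", x$auc_roc, x$auc_pr))
  }
  invisible(x)
}

#' Plot an evaluation report (ROC, PR and decision-curve panels)
#'
#' @param x An `fh_eval_report`.
#' @param which Panels to draw, subset of `c("roc", "pr", "dca")`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fh_eval_report <- function(x, which = c("roc", "pr", "dca"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  if ("roc" %in% which && !is.null(x$roc)) {
    graphics::plot(x$roc$fpr, x$roc$tpr, type = "l",
                   xlab = "1 - specificity", ylab = "sensitivity",
                   main = sprintf("ROC (AUC %.3f)", x$auc_roc), ...)
    graphics::abline(0, 1, lty = 3)
  }
  if ("pr" %in% which && !is.null(x$pr)) {
    graphics::plot(x$pr$recall, x$pr$precision, type = "l", ylim = c(0, 1),
                   xlab = "recall", ylab = "precision",
                   main = sprintf("PR (AUC %.3f)", x$auc_pr), ...)
  }
  if ("dca" %in% which) {
    graphics::plot(x$dca$threshold, x$dca$net_benefit, type = "l",
                   xlab = "threshold probability", ylab = "net benefit",
                   main = "Decision curve",
                   ylim = range(c(x$dca$net_benefit, x$dca$treat_all, 0)), ...)
    graphics::lines(x$dca$threshold, x$dca$treat_all, lty = 2)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

#' Serialize an evaluation report to JSON (and curves to CSV)
#'
#' @param report An `fh_eval_report`.
#' @param path Output JSON path; curve CSVs are written next to it with
#'   suffixes `_roc.csv`, `_pr.csv`, `_dca.csv`.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(report, path) {
  core <- list(n = report$n, threshold = report$threshold,
               counts = as.list(report$counts),
               sensitivity = report$sensitivity,
               specificity = report$specificity,
               balanced_accuracy = report$balanced_accuracy, f1 = report$f1,
               auc_roc = report$auc_roc, auc_pr = report$auc_pr)
  jsonlite::write_json(core, path, auto_unbox = TRUE, digits = NA)
  stem <- sub("\\.json$", "", path)
  if (!is.null(report$roc)) {
    utils::write.csv(report$roc, paste0(stem, "_roc.csv"), row.names = FALSE)
    utils::write.csv(report$pr, paste0(stem, "_pr.csv"), row.names = FALSE)
  }
  utils::write.csv(report$dca, paste0(stem, "_dca.csv"), row.names = FALSE)
  invisible(path)
}
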