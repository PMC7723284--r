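# Confusion-matrix metric suite: accuracy, precision (PPV), recall (TPR),
# specificity (TNR), F1, Matthews correlation coefficient, rank-based
# AUROC, and the region x task report layout.

#' Build a binary confusion matrix
#'
#' The positive class is the first element of the task pair (the
#' disease-ward class).
#'
#' @param y_true,y_pred equal-length label vectors over the task's two
#'   classes.
#' @param positive_class label counted as positive.
#' @return a `confusion_matrix` list: `TP`, `TN`, `FP`, `FN`,
#'   `positive_class`.
#' @export
confusion <- function(y_true, y_pred, positive_class) {
  if (!length(y_true) || length(y_true) != length(y_pred)) {
    stopf("y_true and y_pred must be non-empty and of equal length")
  }
  labels <- unique(c(y_true, y_pred))
  if (!positive_class %in% labels) stopf("positive_class not among the labels")
  if (length(setdiff(labels, c(positive_class, setdiff(labels, positive_class)[1]))) > 0) {
    stopf("labels must span exactly two classes")
  }
  pos_t <- y_true == positive_class
  pos_p <- y_pred == positive_class
  structure(
    list(
      TP = sum(pos_t & pos_p), TN = sum(!pos_t & !pos_p),
      FP = sum(!pos_t & pos_p), FN = sum(pos_t & !pos_p),
      positive_class = positive_class
    ),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf(
    "<confusion_matrix (+%s): TP %d, FN %d, FP %d, TN %d>\n",
    x$positive_class, x$TP, x$FN, x$FP, x$TN
  ))
  invisible(x)
}

#' Metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` and F1 `2PR/(P+R)` are reported
#' as percentages in `[0, 100]`; MCC
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` on `[-1, 1]`.
#' A metric with a zero denominator is reported `NA` (undefined); MCC is 0
#' when any marginal count is 0.
#'
#' @param cm a `confusion_matrix`.
#' @return a `metrics_report` list: `accuracy`, `precision`, `recall`,
#'   `specificity`, `f1`, `mcc`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  TP <- cm$TP
  TN <- cm$TN
  FP <- cm$FP
  FN <- cm$FN
  total <- TP + TN + FP + FN
  if (total == 0) stopf("empty confusion matrix")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  precision <- ratio(TP, TP + FP)
  recall <- ratio(TP, TP + FN)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  marg <- c(TP + FP, TP + FN, TN + FP, TN + FN)
  mcc <- if (any(marg == 0)) {
    0
  } else {
    (TP * TN - FP * FN) / sqrt(prod(marg))
  }
  structure(
    list(
      accuracy = ratio(TP + TN, total),
      precision = precision, recall = recall,
      specificity = ratio(TN, TN + FP),
      f1 = f1, mcc = mcc
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v)
  cat(sprintf(
    "<metrics: acc %s%%, prec %s%%, rec %s%%, spec %s%%, F1 %s%%, MCC %s>\n",
    fmt(x$accuracy), fmt(x$precision), fmt(x$recall), fmt(x$specificity),
    fmt(x$f1), if (is.na(x$mcc)) "NA" else sprintf("%.4f", x$mcc)
  ))
  invisible(x)
}

#' F1 from precision and recall
#'
#' `F1 = 2PR / (P + R)`, on whatever scale `P` and `R` share.
#'
#' @param precision,recall numeric (percent or proportion).
#' @return F1 on the same scale.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, NA_real_,
    2 * precision * recall / (precision + recall)
  )
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outscores a random negative, with ties counted 0.5 (average ranks).
#'
#' @param scores numeric scores in favor of the positive class.
#' @param y_true labels.
#' @param positive_class label counted as positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, y_true, positive_class = sort_c(unique(y_true))[1]) {
  stopifnot(length(scores) == length(y_true))
  pos <- y_true == positive_class
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Region x task performance report
#'
#' Builds the reporting layout used for the trained classifiers: one row
#' per region plus one ensemble row; per task a block of Precision,
#' Recall, F1-score, Accuracy, MCC and AUROC (percentages to two decimals,
#' MCC to four).  The positive class of each task is its first (disease-
#' ward) element.
#'
#' @param decisions a decisions data frame from [predict.tvp_ensemble()]:
#'   columns `subject_id`, `class_label`, `task`, `unit`, `S_i`,
#'   `predicted`.
#' @param units row order; defaults to the six region abbreviations plus
#'   `"ensemble"`.
#' @return a data frame with `unit` plus `<task>.<metric>` columns;
#'   missing cells are `NA` with a warning.
#' @export
report_table <- function(decisions,
                         units = c("LH", "RH", "LA", "RA", "LI", "RI", "ensemble")) {
  needed <- c("subject_id", "class_label", "task", "unit", "S_i", "predicted")
  stopifnot(all(needed %in% names(decisions)))
  tasks_seen <- unique(decisions$task)
  out <- data.frame(unit = units, stringsAsFactors = FALSE)
  for (tn in tasks_seen) {
    pos <- strsplit(tn, "v", fixed = TRUE)[[1]][1]
    for (u in units) {
      sub <- decisions[decisions$task == tn & decisions$unit == u, ]
      cols <- paste(tn, c("precision", "recall", "f1", "accuracy", "mcc", "auroc"),
        sep = "."
      )
      if (!nrow(sub)) {
        warning(sprintf("no decisions for unit %s, task %s", u, tn))
        out[out$unit == u, cols] <- NA_real_
        next
      }
      cm <- confusion(sub$class_label, sub$predicted, pos)
      mt <- metrics(cm)
      au <- tryCatch(100 * auroc(sub$S_i, sub$class_label, pos),
        error = function(e) NA_real_
      )
      vals <- c(
        round(mt$precision, 2), round(mt$recall, 2), round(mt$f1, 2),
        round(mt$accuracy, 2), round(mt$mcc, 4), round(au, 2)
      )
      out[out$unit == u, cols] <- as.list(vals)
    }
  }
  out
}
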