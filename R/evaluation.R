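## Performance metrics: rank-statistic ROC/AUC (midrank tie handling),
## confusion-matrix metrics with explicit degenerate flags, full model
## evaluation reports and side-by-side model comparison tables.

#' Area under the ROC curve via the rank statistic
#'
#' AUC computed from midranks (equivalent to the trapezoidal area under the
#' empirical ROC curve, and to U/(n1*n0) of the Mann-Whitney statistic).
#' Invariant under strictly increasing transforms of the scores.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary truth (0/1, logical, or a factor/character with two
#'   values where the larger sorted value is positive).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) {
    lev <- sort(unique(as.character(labels)))
    if (length(lev) != 2) stop("roc_auc: need exactly two classes present")
    labels <- as.integer(as.character(labels) == lev[2])
  }
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("roc_auc: both classes must be present")
  if (length(scores) != length(labels)) stop("roc_auc: length mismatch")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Points of the empirical ROC curve
#' @param scores,labels as in \code{roc_auc}.
#' @return data.frame with columns threshold, fpr, tpr.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]; labels <- labels[ord]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  keep <- !duplicated(scores, fromLast = TRUE)  # one point per threshold
  tpr <- cumsum(labels == 1)[keep] / n1
  fpr <- cumsum(labels == 0)[keep] / n0
  data.frame(threshold = c(Inf, scores[keep]),
             fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Confusion-matrix metrics for one positive class
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), balanced accuracy
#' (sens+spec)/2, precision TP/(TP+FP), F1, and overall accuracy. Metrics
#' with a zero denominator are reported as 0 with a \code{degenerate} flag
#' rather than raising, so batch comparison tables never abort.
#'
#' @param pred predicted labels.
#' @param truth true labels.
#' @param positive_class the class treated as positive (others collapse to
#'   negative, one-vs-rest).
#' @return named list of metrics plus \code{degenerate} (character vector of
#'   undefined metrics).
#' @export
confusion_metrics <- function(pred, truth, positive_class) {
  if (length(pred) != length(truth) || length(pred) == 0)
    stop("confusion_metrics: empty or mismatched input")
  pred_pos <- pred == positive_class
  true_pos <- truth == positive_class
  tp <- sum(pred_pos & true_pos); fn <- sum(!pred_pos & true_pos)
  fp <- sum(pred_pos & !true_pos); tn <- sum(!pred_pos & !true_pos)
  degenerate <- character()
  safe_div <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); 0 } else num / den
  }
  sens <- safe_div(tp, tp + fn, "sensitivity")
  spec <- safe_div(tn, tn + fp, "specificity")
  prec <- safe_div(tp, tp + fp, "precision")
  f1 <- safe_div(2 * prec * sens, prec + sens, "f1")
  list(sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2, precision = prec, f1 = f1,
       accuracy = mean(pred == truth),
       counts = c(tp = tp, fn = fn, fp = fp, tn = tn),
       degenerate = degenerate)
}

#' Evaluate a trained model on labelled data
#'
#' Per-class one-vs-rest AUC (from each class's predicted probability;
#' binary: AUC of the pathogenic probability), overall top-1 accuracy,
#' per-class sensitivity/specificity/balanced accuracy/precision/F1, the
#' confusion matrix and ROC points. Classes of the task alphabet absent
#' from the truth get NA AUC and are listed in \code{undefined_classes}.
#'
#' @param model a \code{cnv_model}.
#' @param x feature matrix compatible with the model.
#' @param labels true labels.
#' @return list of class \code{cnv_eval_report}.
#' @export
evaluate_model <- function(model, x, labels) {
  labels <- as.character(labels)
  preds <- predict(model, x)
  classes <- model$task$classes
  per_class <- list()
  auc <- stats::setNames(rep(NA_real_, length(classes)), classes)
  roc <- list()
  undefined <- character()
  for (cl in classes) {
    if (!any(labels == cl) || all(labels == cl)) {
      undefined <- c(undefined, cl)
    } else {
      auc[cl] <- roc_auc(preds[[cl]], as.integer(labels == cl))
      roc[[cl]] <- roc_points(preds[[cl]], as.integer(labels == cl))
    }
    per_class[[cl]] <- confusion_metrics(preds$label, labels, cl)
  }
  cm <- table(truth = factor(labels, classes),
              predicted = factor(preds$label, classes))
  out <- list(task = model$task, auc = auc, accuracy = mean(preds$label == labels),
              per_class = per_class, confusion = cm, roc = roc,
              undefined_classes = undefined, n = length(labels))
  class(out) <- "cnv_eval_report"
  out
}

#' @export
print.cnv_eval_report <- function(x, ...) {
  cat(sprintf("Evaluation (%s / %s, n = %d): accuracy %.3f\n",
              x$task$task, x$task$cnv_type, x$n, x$accuracy))
  for (cl in names(x$auc))
    cat(sprintf("  %-24s AUC %s  balanced acc %.3f  sens %.3f  spec %.3f\n",
                cl,
                if (is.na(x$auc[cl])) "   NA" else sprintf("%.3f", x$auc[cl]),
                x$per_class[[cl]]$balanced_accuracy,
                x$per_class[[cl]]$sensitivity, x$per_class[[cl]]$specificity))
  invisible(x)
}

#' Build an evaluation report from an external tool's predicted labels
#'
#' For comparison harnesses: accepts a predictions table (record label per
#' CNV) from another classifier and computes the same per-class
#' label-based metrics (AUC is unavailable without scores and reported NA).
#'
#' @param pred predicted labels from the external tool.
#' @param truth true labels.
#' @param task a \code{cnv_task} defining the class alphabet.
#' @return a \code{cnv_eval_report}.
#' @export
external_report <- function(pred, truth, task) {
  pred <- as.character(pred); truth <- as.character(truth)
  bad <- !pred %in% task$classes
  if (any(bad)) stop("external_report: prediction outside class alphabet: ",
                     pred[bad][1])
  per_class <- lapply(stats::setNames(task$classes, task$classes),
                      function(cl) confusion_metrics(pred, truth, cl))
  cm <- table(truth = factor(truth, task$classes),
              predicted = factor(pred, task$classes))
  out <- list(task = task,
              auc = stats::setNames(rep(NA_real_, length(task$classes)),
                                    task$classes),
              accuracy = mean(pred == truth), per_class = per_class,
              confusion = cm, roc = list(),
              undefined_classes = character(), n = length(truth))
  class(out) <- "cnv_eval_report"
  out
}

#' Side-by-side comparison of two evaluation reports
#'
#' Aligns per-class metrics of two reports over the same task; the better
#' value per cell is marked. Errors if the class alphabets differ.
#'
#' @param report_a,report_b \code{cnv_eval_report}s over the same classes.
#' @param names_ab display names for the two models.
#' @return data.frame with class, metric, both values and a \code{better}
#'   marker ("a", "b" or "=").
#' @export
compare_models <- function(report_a, report_b, names_ab = c("a", "b")) {
  if (!identical(report_a$task$classes, report_b$task$classes))
    stop("compare_models: class alphabets differ")
  metrics <- c("balanced_accuracy", "sensitivity", "specificity",
               "precision", "f1")
  rows <- list()
  for (cl in report_a$task$classes) {
    for (m in metrics) {
      va <- report_a$per_class[[cl]][[m]]
      vb <- report_b$per_class[[cl]][[m]]
      rows[[length(rows) + 1]] <- data.frame(
        class = cl, metric = m, a = va, b = vb,
        better = if (isTRUE(all.equal(va, vb))) "="
                 else if (va > vb) "a" else "b")
    }
  }
  out <- do.call(rbind, rows)
  names(out)[3:4] <- names_ab
  out
}

#' Write a comparison table as TSV
#' @param table output of \code{compare_models}.
#' @param path output path.
#' @export
write_comparison <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
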