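# Multiclass evaluation: confusion matrices, one-vs-rest reduction of
# accuracy / precision / recall / specificity / F-1, macro averaging, and
# ROC/AUC by threshold sweep. Macro F-1 is the unweighted mean of per-class
# F-1 values (not the harmonic combination of macro precision and recall).

#' Confusion matrix from paired label vectors
#'
#' @param true_labels,predicted_labels Equal-length vectors of class labels
#'   (character from [class_labels()] or integer codes 0..3).
#' @return 4 x 4 integer matrix, rows = true class, columns = predicted.
#' @export
confusion <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("true and predicted label vectors differ in length")
  to_chr <- function(v) if (is.numeric(v)) class_decoding(v) else v
  t_f <- factor(to_chr(true_labels), levels = class_labels())
  p_f <- factor(to_chr(predicted_labels), levels = class_labels())
  if (anyNA(t_f) || anyNA(p_f)) stop("labels outside the known classes")
  cm <- table(true = t_f, predicted = p_f)
  matrix(as.integer(cm), 4, 4, dimnames = list(true = class_labels(),
                                               predicted = class_labels()))
}

#' One-vs-rest reduction of a confusion matrix
#'
#' @param cm Confusion matrix (rows true, columns predicted).
#' @param cls Class name or 0-based code.
#' @return Named integer vector `(TP, FN, FP, TN)`.
#' @export
one_vs_rest <- function(cm, cls) {
  if (is.numeric(cls)) cls <- class_decoding(cls)
  i <- match(cls, rownames(cm))
  if (is.na(i)) stop("unknown class: ", cls)
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, FN = fn, FP = fp, TN = tn)
}

#' Basic one-vs-rest metrics
#'
#' Accuracy (TP+TN)/total, precision TP/(TP+FP), recall TP/(TP+FN),
#' specificity TN/(TN+FP), F-1 = 2 x precision x recall /
#' (precision + recall). Zero-denominator cases return `NA` (undefined);
#' F-1 is 0 by convention when precision or recall is undefined or both are
#' zero.
#'
#' @param TP,FN,FP,TN Non-negative counts, not all zero.
#' @return Named numeric vector
#'   `(accuracy, precision, recall, specificity, f1)`.
#' @export
basic_metrics <- function(TP, FN, FP, TN) {
  total <- TP + FN + FP + TN
  if (total == 0) stop("empty confusion: all counts zero")
  prec <- if (TP + FP == 0) NA_real_ else TP / (TP + FP)
  rec <- if (TP + FN == 0) NA_real_ else TP / (TP + FN)
  spec <- if (TN + FP == 0) NA_real_ else TN / (TN + FP)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) 0
        else 2 * prec * rec / (prec + rec)
  c(accuracy = (TP + TN) / total, precision = prec, recall = rec,
    specificity = spec, f1 = f1)
}

#' Per-class and macro metric report
#'
#' Applies [one_vs_rest()] + [basic_metrics()] to each class and
#' macro-averages with equal class weight (undefined values excluded with
#' `na.rm`). The pooled (micro) accuracy `sum(diag)/total` is also reported.
#'
#' @param cm A 4 x 4 confusion matrix.
#' @return An object of class `"metric_report"`: list with `per_class`
#'   (4 x 5 matrix), `macro` (named vector), `micro_accuracy`, `cm`.
#' @export
macro_report <- function(cm) {
  per <- t(vapply(rownames(cm),
                  function(cl) do.call(basic_metrics,
                                       as.list(one_vs_rest(cm, cl))),
                  numeric(5)))
  macro <- colMeans(per, na.rm = TRUE)
  structure(list(per_class = per, macro = macro,
                 micro_accuracy = sum(diag(cm)) / sum(cm), cm = cm),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("per-class (one-vs-rest):\n")
  print(round(x$per_class, 4))
  cat("macro: ", paste(sprintf("%s %.4f", names(x$macro), x$macro),
                       collapse = ", "), "\n")
  cat(sprintf("pooled accuracy: %.4f\n", x$micro_accuracy))
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps thresholds over the unique scores (plus infinite endpoints so the
#' curve runs from (0,0) to (1,1)) and integrates by the trapezoid rule.
#' With ties this equals the rank statistic
#' `(#\{pos > neg\} + 0.5 #\{pos = neg\}) / (n_pos * n_neg)`.
#'
#' @param scores Real-valued classifier scores.
#' @param positives Logical vector, `TRUE` for positive samples.
#' @return List with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, positives) {
  positives <- as.logical(positives)
  if (length(scores) != length(positives))
    stop("scores and positives differ in length")
  np <- sum(positives); nn <- sum(!positives)
  if (np == 0 || nn == 0)
    stop("ROC needs at least one positive and one negative sample")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(t) sum(scores[positives] >= t) / np, numeric(1))
  fpr <- vapply(th, function(t) sum(scores[!positives] >= t) / nn, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = th, fpr = fpr, tpr = tpr), auc = auc)
}

#' One-vs-rest multiclass AUC
#'
#' Per-class ROC/AUC using each class's probability column against a binary
#' indicator of that class, macro-averaged with equal weight. A class absent
#' from `true_labels` gets `NA` and is excluded from the macro with a
#' warning.
#'
#' @param prob_matrix n x 4 matrix of class probabilities (rows sum to 1).
#' @param true_labels Length-n vector of true labels.
#' @return List with `per_class` (named numeric, possibly `NA`) and `macro`.
#' @export
multiclass_auc <- function(prob_matrix, true_labels) {
  if (is.numeric(true_labels)) true_labels <- class_decoding(true_labels)
  if (nrow(prob_matrix) != length(true_labels))
    stop("probability matrix and labels differ in length")
  per <- vapply(seq_along(class_labels()), function(k) {
    pos <- true_labels == class_labels()[k]
    if (!any(pos) || all(pos)) return(NA_real_)
    roc_auc(prob_matrix[, k], pos)$auc
  }, numeric(1))
  names(per) <- class_labels()
  if (anyNA(per))
    warning("class(es) absent from true labels excluded from macro AUC: ",
            paste(names(per)[is.na(per)], collapse = ", "))
  list(per_class = per, macro = mean(per, na.rm = TRUE))
}
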