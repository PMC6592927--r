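# Evaluation surface: confusion matrix, scalar metrics (accuracy, error,
# sensitivity, specificity, precision, F1, Cohen's kappa), one-vs-all
# ROC/AUC, and class-distribution reporting.

#' Confusion matrix
#'
#' Rows are the expert (true) classes, columns the predicted classes, both in
#' the order I, II, III, IV (or the supplied `classes`).
#'
#' @param truth,pred Equal-length label vectors.
#' @param classes Class order; defaults to [EMA_CLASSES].
#' @return Integer matrix with class dimnames.
#' @export
confusion_matrix <- function(truth, pred, classes = EMA_CLASSES) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) {
    stop_emaclass("truth and pred differ in length: ", length(truth), " vs ",
                  length(pred), class = "emaclass_validation_error")
  }
  bad <- setdiff(unique(c(truth, pred)), classes)
  if (length(bad) > 0) {
    stop_emaclass("unknown label(s): ", paste(bad, collapse = ", "),
                  class = "emaclass_validation_error")
  }
  tf <- factor(truth, levels = classes)
  pf <- factor(pred, levels = classes)
  m <- table(truth = tf, predicted = pf)
  matrix(as.integer(m), nrow = length(classes),
         dimnames = list(truth = classes, predicted = classes))
}

# binary reduction of a k-class confusion matrix: `cls` vs rest
binary_reduction <- function(cm, cls) {
  i <- match(cls, rownames(cm))
  tp <- cm[i, i]
  fn <- sum(cm[i, -i])
  fp <- sum(cm[-i, i])
  tn <- sum(cm[-i, -i])
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Scalar performance metrics from a confusion matrix
#'
#' Computes overall accuracy (`trace / total`) and classification error
#' (`1 - accuracy`), Cohen's kappa (`(p_o - p_e) / (1 - p_e)` with the chance
#' agreement `p_e` from the row/column marginals), and, for every class,
#' the one-vs-rest sensitivity, specificity, precision and F1 (harmonic mean
#' of precision and sensitivity). The headline `sensitivity`, `specificity`,
#' `precision` and `f1` fields are those of `positive_class`. Ratios with a
#' zero denominator are reported as `NA` and listed in `$undefined` rather
#' than silently set to 0.
#'
#' @param cm Square confusion matrix with class dimnames (rows = truth).
#' @param positive_class Class used for the headline binary metrics.
#' @param exclude_inconclusive If `TRUE`, samples *predicted* as class IV
#'   (equivocal) are dropped from the accuracy/error denominator; recorded in
#'   the output when on.
#' @return A list of class `metrics_report` (see fields above, plus
#'   `per_class` data.frame and `macro` averages).
#' @export
scalar_metrics <- function(cm, positive_class = "I",
                           exclude_inconclusive = FALSE) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm),
            !is.null(rownames(cm)), all(rownames(cm) == colnames(cm)))
  classes <- rownames(cm)
  stopifnot(positive_class %in% classes)
  total <- sum(cm)
  if (total <= 0) {
    stop_emaclass("confusion matrix is empty", class = "emaclass_validation_error")
  }
  undefined <- character(0)

  acc_cm <- cm
  if (exclude_inconclusive && "IV" %in% classes) {
    acc_cm <- cm[, setdiff(classes, "IV"), drop = FALSE]
  }
  acc_total <- sum(acc_cm)
  correct <- sum(vapply(colnames(acc_cm),
                        function(k) cm[k, k], numeric(1)))
  accuracy <- safe_ratio(correct, acc_total)
  if (is.na(accuracy)) undefined <- c(undefined, "accuracy")
  error <- if (is.na(accuracy)) NA_real_ else 1 - accuracy

  # Cohen's kappa from the full matrix
  p_o <- sum(diag(cm)) / total
  p_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (1 - p_e < 1e-12) {
    kappa <- NA_real_
    undefined <- c(undefined, "kappa")
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
  }

  per_class <- do.call(rbind, lapply(classes, function(cls) {
    b <- binary_reduction(cm, cls)
    sens <- safe_ratio(b["tp"], b["tp"] + b["fn"])
    spec <- safe_ratio(b["tn"], b["tn"] + b["fp"])
    prec <- safe_ratio(b["tp"], b["tp"] + b["fp"])
    f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_
          else 2 * prec * sens / (prec + sens)
    data.frame(class = cls, sensitivity = unname(sens),
               specificity = unname(spec), precision = unname(prec),
               f1 = unname(f1))
  }))
  for (fld in c("sensitivity", "specificity", "precision", "f1")) {
    if (any(is.na(per_class[[fld]]))) {
      undefined <- c(undefined,
                     paste0(fld, "(", per_class$class[is.na(per_class[[fld]])],
                            ")"))
    }
  }
  head_row <- per_class[per_class$class == positive_class, ]

  structure(list(
    accuracy = accuracy,
    error = error,
    sensitivity = head_row$sensitivity,
    specificity = head_row$specificity,
    precision = head_row$precision,
    f1 = head_row$f1,
    kappa = kappa,
    per_class = per_class,
    macro = list(sensitivity = mean(per_class$sensitivity, na.rm = TRUE),
                 specificity = mean(per_class$specificity, na.rm = TRUE),
                 f1 = mean(per_class$f1, na.rm = TRUE)),
    positive_class = positive_class,
    exclude_inconclusive = exclude_inconclusive,
    undefined = unique(undefined),
    confusion = cm
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("EmA classification metrics (positive class:", x$positive_class, ")\n")
  cat(sprintf("  accuracy    %.4f   error %.4f\n", x$accuracy, x$error))
  cat(sprintf("  sensitivity %.4f   specificity %.4f\n",
              x$sensitivity, x$specificity))
  cat(sprintf("  F1          %.4f   kappa %.4f\n", x$f1, x$kappa))
  if (!is.null(x$auc_per_class)) {
    cat("  one-vs-all AUC:",
        paste(sprintf("%s=%.4f", names(x$auc_per_class), x$auc_per_class),
              collapse = "  "), "\n")
  }
  if (length(x$undefined) > 0) {
    cat("  undefined (zero denominator):",
        paste(x$undefined, collapse = ", "), "\n")
  }
  cat("  confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' One-vs-all area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with ties counted one half; identical to
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric score per sample (larger = more positive).
#' @param truth Logical (or 0/1) indicator of the positive class.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) when only one class is
#'   present.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), all(!is.na(truth)))
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) {
    warning("AUC undefined: only one class present in truth")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical ROC curve points
#'
#' Thresholds are all unique score values plus infinite endpoints; a sample
#' is called positive when its score is >= the threshold.
#'
#' @inheritParams roc_auc
#' @return data.frame with columns `fpr`, `tpr`, `threshold`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  n_pos <- sum(truth); n_neg <- sum(!truth)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth) / max(n_pos, 1),
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !truth) / max(n_neg, 1),
                numeric(1))
  data.frame(fpr = fpr, tpr = tpr, threshold = thr)
}

#' Class shares as percentages
#'
#' @param class_counts Non-negative counts (any length).
#' @return Percentages `100 * count / total`, rounded half-up to two
#'   decimals.
#' @export
class_shares <- function(class_counts) {
  stopifnot(all(class_counts >= 0), sum(class_counts) > 0)
  round_half_up(100 * class_counts / sum(class_counts), 2)
}

#' Full evaluation of pooled predictions
#'
#' Builds the confusion matrix, all scalar metrics and the per-class
#' one-vs-all AUC from pooled held-out predictions and scores.
#'
#' @param truth True labels.
#' @param pred Predicted labels.
#' @param scores Optional n x 4 matrix of per-class scores (for ROC/AUC).
#' @param positive_class Headline class for binary metrics.
#' @param exclude_inconclusive See [scalar_metrics()].
#' @return A `metrics_report` with an `auc_per_class` field (and
#'   `roc_curves`, a named list of data.frames) when scores are given.
#' @export
evaluate_predictions <- function(truth, pred, scores = NULL,
                                 positive_class = "I",
                                 exclude_inconclusive = FALSE) {
  truth <- check_labels(truth)
  pred <- check_labels(pred)
  cm <- confusion_matrix(truth, pred)
  rep <- scalar_metrics(cm, positive_class = positive_class,
                        exclude_inconclusive = exclude_inconclusive)
  if (!is.null(scores)) {
    stopifnot(is.matrix(scores), nrow(scores) == length(truth),
              ncol(scores) == 4)
    colnames(scores) <- EMA_CLASSES
    auc <- vapply(EMA_CLASSES, function(cls) {
      ind <- truth == cls
      if (!any(ind) || all(ind)) return(NA_real_)
      roc_auc(scores[, cls], ind)
    }, numeric(1))
    rep$auc_per_class <- auc
    rep$roc_curves <- lapply(stats::setNames(EMA_CLASSES, EMA_CLASSES),
                             function(cls) roc_curve(scores[, cls],
                                                     truth == cls))
  }
  rep$class_shares <- class_shares(table(truth))
  rep
}
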