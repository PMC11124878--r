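#' Confusion matrix from label vectors
#'
#' Rows are true labels, columns are predicted labels; entry (i, j) counts
#' items with true label i predicted as j.
#'
#' @param truth,predicted equal-length label vectors; every value must occur
#'   in `labels`.
#' @param labels the ordered label set (default: sorted union of both
#'   vectors).
#' @return a K x K integer matrix of class `confusion_matrix` with dimnames
#'   `true` / `predicted`.
#' @export
confusion_matrix <- function(truth, predicted,
                             labels = sort(unique(c(truth, predicted)))) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  unknown <- setdiff(unique(c(truth, predicted)), labels)
  if (length(unknown))
    stop("label(s) not in the label list: ", paste(unknown, collapse = ", "))
  k <- length(labels)
  cm <- matrix(0L, k, k, dimnames = list(true = labels, predicted = labels))
  ti <- match(truth, labels); pi_ <- match(predicted, labels)
  for (i in seq_along(ti)) cm[ti[i], pi_[i]] <- cm[ti[i], pi_[i]] + 1L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * P * R / (P + R)`, with the convention that F1 is 0 when
#' both precision and recall are 0.
#'
#' @param precision,recall numeric vectors in [0, 1].
#' @return numeric vector of F1 scores.
#' @export
f1_score <- function(precision, recall) {
  denom <- precision + recall
  ifelse(denom > 0, 2 * precision * recall / denom, 0)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.005 -> 0.01), the convention used
#' when comparing computed metrics against tables printed at fixed
#' precision; base R's `round()` rounds ties to even instead.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Per-class and aggregate classification metrics
#'
#' Computes, from a confusion matrix, per-class precision `TP / (TP + FP)`,
#' recall (sensitivity) `TP / (TP + FN)` and F1, plus overall accuracy
#' (correct / total), macro averages (unweighted class means) and weighted
#' (support-weighted) averages. A class with a zero denominator gets metric 0
#' with a warning. For single-label multiclass data the support-weighted
#' recall equals the accuracy identically.
#'
#' @param cm a [confusion_matrix()].
#' @return an object of class `metrics_report`: list with `per_class`
#'   (data.frame: class, support, precision, recall, f1), `accuracy`,
#'   `macro` and `weighted` (each a named vector precision/recall/f1).
#' @export
classification_metrics <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix is empty")
  tp <- diag(cm)
  support <- rowSums(cm)
  pred_tot <- colSums(cm)
  zero_p <- pred_tot == 0; zero_r <- support == 0
  if (any(zero_p))
    warning("class(es) never predicted (precision set to 0): ",
            paste(rownames(cm)[zero_p], collapse = ", "))
  if (any(zero_r))
    warning("class(es) with zero support (recall set to 0): ",
            paste(rownames(cm)[zero_r], collapse = ", "))
  precision <- ifelse(zero_p, 0, tp / pred_tot)
  recall <- ifelse(zero_r, 0, tp / support)
  f1 <- f1_score(precision, recall)
  w <- support / total
  structure(list(
    per_class = data.frame(class = rownames(cm), support = as.integer(support),
                           precision = precision, recall = recall, f1 = f1,
                           row.names = NULL),
    accuracy = sum(tp) / total,
    macro = c(precision = mean(precision), recall = mean(recall),
              f1 = mean(f1)),
    weighted = c(precision = sum(w * precision), recall = sum(w * recall),
                 f1 = sum(w * f1))),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3L, ...) {
  cat("Classification metrics\n")
  pc <- x$per_class
  pc[c("precision", "recall", "f1")] <-
    lapply(pc[c("precision", "recall", "f1")], round, digits)
  print(pc, row.names = FALSE)
  cat(sprintf("accuracy: %.*f\n", digits, x$accuracy))
  cat(sprintf("macro    P/R/F1: %.*f / %.*f / %.*f\n", digits, x$macro[1],
              digits, x$macro[2], digits, x$macro[3]))
  cat(sprintf("weighted P/R/F1: %.*f / %.*f / %.*f\n", digits, x$weighted[1],
              digits, x$weighted[2], digits, x$weighted[3]))
  invisible(x)
}

#' Evaluate a trained model on a window set
#'
#' Predictions are the argmax of the forward probabilities (ties broken
#' toward the lowest class index). With `aggregation = "repetition"` (the
#' default) all windows belonging to one repetition are pooled into a single
#' majority-vote prediction, ties broken toward the class with the highest
#' mean probability; the report then counts repetitions, not windows.
#'
#' @param model a trained `resnet1d_model`.
#' @param test_set a [make_window_set()] object.
#' @param aggregation `"repetition"` (default) or `"window"`.
#' @return list with `metrics` (a `metrics_report`), `confusion` (a
#'   `confusion_matrix`), and `predictions` (data.frame of truth/prediction
#'   per evaluated item).
#' @export
evaluate <- function(model, test_set,
                     aggregation = c("repetition", "window")) {
  aggregation <- match.arg(aggregation)
  if (dim(test_set$x)[3] == 0) stop("empty test set")
  probs <- .predict_probs(model, test_set$x)
  classes <- test_set$classes
  if (aggregation == "window") {
    pred <- classes[max.col(probs, ties.method = "first")]
    truth <- classes[test_set$y]
  } else {
    keys <- unique(test_set$rep_key)
    pred <- character(0); truth_i <- integer(0)
    pred_i <- vapply(keys, function(k) {
      rows <- which(test_set$rep_key == k)
      votes <- max.col(probs[rows, , drop = FALSE], ties.method = "first")
      tab <- tabulate(votes, nbins = length(classes))
      top <- which(tab == max(tab))
      if (length(top) > 1L) {
        mean_p <- colMeans(probs[rows, , drop = FALSE])
        top <- top[which.max(mean_p[top])]
      }
      top
    }, integer(1))
    truth_i <- vapply(keys, function(k)
      test_set$y[which(test_set$rep_key == k)[1]], integer(1))
    pred <- classes[pred_i]
    truth <- classes[truth_i]
  }
  cm <- confusion_matrix(truth, pred, labels = classes)
  list(metrics = classification_metrics(cm), confusion = cm,
       predictions = data.frame(truth = truth, predicted = pred))
}
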