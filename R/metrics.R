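## Classification metrics: overall accuracy, one-vs-rest class counts,
## macro precision/recall/F1 (the harmonic-mean form), confusion matrix,
## and per-class ROC / precision-recall curves from softmax scores.

#' Compute a MetricsReport from labels, predictions and scores
#'
#' Accuracy is overall sample accuracy.  Precision, recall and F1 are
#' computed per class one-vs-rest (precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F1 their harmonic mean) and macro-averaged (unweighted
#' class mean); micro averaging is available via \code{average}.
#' Classes with no positive predictions get precision 0 by convention.
#'
#' @param labels integer true class indices (1-based).
#' @param predicted integer predicted class indices.
#' @param scores optional classes x samples score (softmax) matrix for
#'   ROC/PR curves and AUC.
#' @param n_classes number of classes.
#' @param average \code{"macro"} (default) or \code{"micro"}.
#' @return a \code{\linkS4class{MetricsReport}}.
#' @export
classificationMetrics <- function(labels, predicted, scores = NULL,
                                  n_classes = max(labels),
                                  average = c("macro", "micro")) {
  average <- match.arg(average)
  n <- length(labels)
  stopifnot(length(predicted) == n)
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = seq_len(n_classes),
                               pred = seq_len(n_classes)))
  for (i in seq_len(n)) cm[labels[i], predicted[i]] <- cm[labels[i], predicted[i]] + 1L
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- n - tp - fp - fn
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  acc <- sum(tp) / n
  roc <- list(); pr <- list(); auc <- rep(NA_real_, n_classes)
  if (!is.null(scores)) {
    for (k in seq_len(n_classes)) {
      cur <- rocCurve(labels == k, scores[k, ])
      roc[[k]] <- cur$roc; pr[[k]] <- cur$pr; auc[k] <- cur$auc
    }
  }
  if (average == "micro") {
    mp <- sum(tp) / max(1, sum(tp + fp))
    mr <- sum(tp) / max(1, sum(tp + fn))
    mf <- if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
  } else {
    mp <- mean(prec); mr <- mean(rec); mf <- mean(f1)
  }
  new("MetricsReport", accuracy = acc, macro_precision = mp,
      macro_recall = mr, macro_f1 = mf,
      per_class = data.frame(class = seq_len(n_classes), tp = tp, fp = fp,
                             fn = fn, tn = tn, precision = prec,
                             recall = rec, f1 = f1, auc = auc),
      confusion = cm, roc = roc, pr = pr)
}

#' One-vs-rest ROC and PR curve from scores
#'
#' Threshold sweep over the unique score values; AUC by the trapezoidal
#' rule over the ROC points (equivalently, the rank statistic with ties
#' shared).
#'
#' @param positive logical vector (is the sample a positive).
#' @param score numeric score for the positive class.
#' @return list with \code{roc} (fpr, tpr), \code{pr} (recall, precision)
#'   data frames and \code{auc}.
#' @export
rocCurve <- function(positive, score) {
  o <- order(score, decreasing = TRUE)
  y <- positive[o]; s <- score[o]
  P <- sum(y); N <- sum(!y)
  tps <- cumsum(y); fps <- cumsum(!y)
  keep <- c(diff(s) != 0, TRUE)      # one point per distinct threshold
  tps <- tps[keep]; fps <- fps[keep]
  tpr <- c(0, if (P > 0) tps / P else tps * 0)
  fpr <- c(0, if (N > 0) fps / N else fps * 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  prec <- ifelse(tps + fps > 0, tps / (tps + fps), 1)
  recl <- if (P > 0) tps / P else tps * 0
  list(roc = data.frame(fpr = fpr, tpr = tpr),
       pr = data.frame(recall = recl, precision = prec),
       auc = auc)
}
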