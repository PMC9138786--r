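#' Classification metrics from confusion counts
#'
#' Accuracy, precision, sensitivity (recall), F1 and Matthews correlation
#' coefficient computed directly from the four confusion-matrix counts:
#' \deqn{Acc = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{Prec = TP/(TP+FP), \quad Sen = TP/(TP+FN)}
#' \deqn{F1 = 2\,Prec\,Sen/(Prec+Sen)}
#' \deqn{MCC = (TP\,TN - FP\,FN)/\sqrt{(TP+FP)(TN+FN)(TN+FP)(TP+FN)}}
#' Ratios with a zero denominator are returned as \code{NA}.
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return named numeric vector (Acc, Prec, Sen, F1, MCC).
#' @examples
#' confusionMetrics(tp = 3, fp = 1, tn = 4, fn = 2)
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  total <- tp + fp + tn + fn
  acc <- if (total > 0) (tp + tn) / total else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sen) && prec + sen > 0)
    2 * prec * sen / (prec + sen) else NA_real_
  den <- (tp + fp) * (tn + fn) * (tn + fp) * (tp + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else NA_real_
  c(Acc = acc, Prec = prec, Sen = sen, F1 = f1, MCC = mcc)
}

#' Area under the ROC curve (rank statistic)
#'
#' Computed via the Mann-Whitney rank statistic over all
#' (positive, negative) score pairs, counting ties as one half. Invariant
#' under strictly monotone transforms of the scores.
#'
#' @param labels 0/1 vector.
#' @param scores numeric vector of the same length.
#' @return AUC in [0, 1]; \code{NA} if either class is absent.
#' @export
aucScore <- function(labels, scores) {
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L)
  nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve
#'
#' Step integration of the precision-recall curve over descending score
#' thresholds; tied scores enter as one atomic group, so the result does not
#' depend on the ordering within ties.
#'
#' @param labels 0/1 vector.
#' @param scores numeric vector of the same length.
#' @return AUPR in [0, 1]; \code{NA} if either class is absent.
#' @export
auprScore <- function(labels, scores) {
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L)
  if (nPos == 0L || all(labels == 1L)) return(NA_real_)
  posAt <- rowsum(as.numeric(labels), scores)[, 1L]           # by sorted score
  cntAt <- rowsum(rep(1, length(scores)), scores)[, 1L]
  ord <- order(as.numeric(names(posAt)), decreasing = TRUE)
  tpCum <- cumsum(posAt[ord])
  nCum <- cumsum(cntAt[ord])
  prec <- tpCum / nCum
  rec <- tpCum / nPos
  sum(diff(c(0, rec)) * prec)
}

#' Full metrics report for one score vector
#'
#' Thresholds the scores (default 0.5) for the confusion-count metrics and
#' adds the threshold-free AUC and AUPR. With a single-class input the
#' rank-based and correlation metrics (AUC, AUPR, MCC) are reported as
#' \code{NA} while the remaining metrics are computed.
#'
#' @param labels 0/1 vector of true classes.
#' @param scores numeric predicted probabilities (or any scores for
#'   AUC/AUPR; thresholding assumes probabilities).
#' @param threshold classification threshold, default 0.5.
#' @return named numeric vector:
#'   Acc, Prec, Sen, F1, MCC, AUC, AUPR, TP, FP, TN, FN.
#' @export
computeMetrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  base <- confusionMetrics(tp, fp, tn, fn)
  if (length(unique(labels)) < 2L) base["MCC"] <- NA_real_
  c(base,
    AUC = aucScore(labels, scores),
    AUPR = auprScore(labels, scores),
    TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Assemble a cross-validation metrics report
#'
#' @param perFold data.frame of per-fold metric rows.
#' @return a [MetricsReport-class] with mean and standard deviation rows.
#' @export
metricsReport <- function(perFold) {
  perFold <- as.data.frame(perFold)
  cols <- intersect(c("Acc", "Prec", "Sen", "F1", "MCC", "AUC", "AUPR"),
                    names(perFold))
  summ <- rbind(
    mean = vapply(perFold[cols], mean, numeric(1)),
    sd = vapply(perFold[cols], stats::sd, numeric(1))
  )
  new("MetricsReport", perFold = perFold, summary = as.data.frame(summ))
}
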