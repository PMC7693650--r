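#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a random positive outranks a random negative, with
#' mid-ranks for ties; higher score means positive class.
#'
#' @param scores numeric scores
#' @param labels binary labels (1/TRUE = positive)
#' @return AUC in [0, 1]
#' @export
aucRank <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve
#'
#' Ordered (FPR, TPR) points obtained by sweeping the decision threshold
#' over the distinct scores, plus the trapezoidal area under the curve
#' (which equals the mid-rank Mann-Whitney AUC).
#'
#' @inheritParams aucRank
#' @return list with \code{points} (data.frame fpr, tpr, from (0,0) to
#'   (1,1)) and \code{auc}
#' @export
rocCurve <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  keep <- c(diff(ss) != 0, TRUE)   # one point per distinct threshold
  tpr <- c(0, tp[keep] / n1); fpr <- c(0, fp[keep] / n0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Confusion-matrix metrics at a fixed decision
#'
#' @param pred binary predictions (1 = positive call)
#' @param labels binary truth
#' @return named vector: sensitivity, specificity, ppv, npv, accuracy.
#'   Ratios with a zero denominator are returned as NA (flagged, not zeroed).
#' @export
confusionMetrics <- function(pred, labels) {
  p <- as.integer(as.logical(pred)); y <- as.integer(as.logical(labels))
  tp <- sum(p == 1 & y == 1); fn <- sum(p == 0 & y == 1)
  fp <- sum(p == 1 & y == 0); tn <- sum(p == 0 & y == 0)
  rat <- function(a, b) if (b == 0) NA_real_ else a / b
  c(sensitivity = rat(tp, tp + fn), specificity = rat(tn, tn + fp),
    ppv = rat(tp, tp + fp), npv = rat(tn, tn + fn),
    accuracy = (tp + tn) / length(y))
}

#' Single-marker threshold baseline
#'
#' AUC of one feature column used directly as a decision score, with the
#' orientation flipped if needed so AUC >= 0.5, and a seeded percentile
#' bootstrap confidence interval (class-stratified resampling so every
#' resample contains both classes).
#'
#' @param x numeric marker column
#' @param labels binary labels (1 = HCM)
#' @param nBoot bootstrap resamples (default 2000)
#' @param seed RNG seed
#' @param level confidence level
#' @return list: auc, ciLow, ciHigh, higherIsPositive, nBoot
#' @export
markerBaseline <- function(x, labels, nBoot = 2000L, seed = 1L,
                           level = 0.95) {
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (length(unique(x)) == 1) {
    warning("constant marker column: AUC 0.5 with degenerate CI")
    return(list(auc = 0.5, ciLow = 0.5, ciHigh = 0.5,
                higherIsPositive = TRUE, nBoot = 0L))
  }
  a <- aucRank(x, y)
  higher <- a >= 0.5
  s <- if (higher) x else -x
  a <- aucRank(s, y)
  set.seed(seed)
  ipos <- which(y == 1); ineg <- which(y == 0)
  boot <- numeric(nBoot)
  for (b in seq_len(nBoot)) {
    ii <- c(sample(ipos, length(ipos), replace = TRUE),
            sample(ineg, length(ineg), replace = TRUE))
    boot[b] <- aucRank(s[ii], y[ii])
  }
  qs <- quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  list(auc = a, ciLow = min(qs[1], a), ciHigh = max(qs[2], a),
       higherIsPositive = higher, nBoot = as.integer(nBoot))
}
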