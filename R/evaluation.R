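#' ISH decision rule
#'
#' Calls the HER2 status from fluorescence ISH signal counts (mean green
#' HER2 and orange CEN17 signals over 20 tumour cells): positive when
#' `her2 / cen17 >= 2.0` **or** `her2 >= 6.0`, negative otherwise.
#'
#' @param her2Signals mean HER2 signal count (> 0).
#' @param cen17Signals mean CEN17 signal count (> 0).
#' @return integer status (1 positive, 0 negative), vectorised.
#' @examples
#' ishCall(4, 2)   # ratio exactly 2.0 -> positive
#' ishCall(6, 5)   # ratio 1.2 but 6 signals -> positive
#' ishCall(3, 2)   # fails both clauses -> negative
#' @export
ishCall <- function(her2Signals, cen17Signals) {
  if (any(!is.finite(cen17Signals)) || any(cen17Signals <= 0))
    stop("CEN17 signal counts must be positive")
  if (any(!is.finite(her2Signals)) || any(her2Signals <= 0))
    stop("HER2 signal counts must be positive")
  as.integer(her2Signals / cen17Signals >= 2.0 | her2Signals >= 6.0)
}

#' Map IHC score to HER2 status
#'
#' Scores 0 and 1 are HER2-negative and score 3 is HER2-positive. Score 2 is
#' equivocal: its status must be supplied directly (`status`) or be
#' derivable from ISH signal counts via [ishCall()].
#'
#' @param score IHC score(s) in `{0, 1, 2, 3}`.
#' @param status optional known status for score-2 spots.
#' @param her2Signals,cen17Signals optional ISH counts for score-2 spots.
#' @return integer status vector (0/1).
#' @export
scoreToStatus <- function(score, status = NULL, her2Signals = NULL,
                          cen17Signals = NULL) {
  if (!all(score %in% 0:3))
    stop("invalid IHC score value(s): ",
         paste(unique(setdiff(score, 0:3)), collapse = ", "))
  n <- length(score)
  out <- integer(n)
  out[score %in% c(0, 1)] <- 0L
  out[score == 3] <- 1L
  eq <- which(score == 2)
  for (i in eq) {
    if (!is.null(status) && !is.na(status[i])) {
      out[i] <- as.integer(status[i])
    } else if (!is.null(her2Signals) && !is.na(her2Signals[i]) &&
               !is.null(cen17Signals) && !is.na(cen17Signals[i])) {
      out[i] <- ishCall(her2Signals[i], cen17Signals[i])
    } else {
      stop("unresolved label: score-2 spot without status or ISH counts ",
           "(position ", i, ")")
    }
  }
  out
}

#' Confusion matrix (predicted x true)
#'
#' Entry `(i, j)` counts spots predicted as class `i` whose true class is
#' `j` — the orientation used throughout this package and stated on every
#' printed report.
#'
#' @param yTrue true class labels.
#' @param yPred predicted class labels.
#' @param classes class set (defaults to the sorted union of both vectors).
#' @return `C x C` integer matrix with dimnames
#'   `list(predicted, true)`.
#' @export
confusionMatrix <- function(yTrue, yPred, classes = NULL) {
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length")
  classes <- classes %||% sort(unique(c(yTrue, yPred)))
  if (!all(yTrue %in% classes) || !all(yPred %in% classes))
    stop("labels outside the declared class set")
  tp <- factor(yPred, levels = classes)
  tt <- factor(yTrue, levels = classes)
  m <- unclass(table(predicted = tp, true = tt))
  attr(m, "call") <- NULL
  m
}

#' Balanced accuracy
#'
#' Unweighted mean over classes of the per-class recall
#' `correct_c / true_c` — robust to class imbalance and the headline metric
#' for HER2 scoring. Requires every true class to have at least one sample.
#'
#' @param confusion predicted x true confusion matrix.
#' @return numeric scalar in `[0, 1]`.
#' @examples
#' balancedAccuracy(matrix(c(8, 2, 5, 5), 2, 2))  # mean(8/10, 5/10) = 0.65
#' @export
balancedAccuracy <- function(confusion) {
  trueCounts <- colSums(confusion)
  if (any(trueCounts == 0))
    stop("balanced accuracy undefined: empty true class present")
  mean(diag(as.matrix(confusion)) / trueCounts)
}

#' Support-weighted precision, recall and F1
#'
#' Per-class precision, recall and F1, each averaged with weights
#' `true_c / n` (the class supports). The weighted recall algebraically
#' equals the overall accuracy. Classes never predicted get per-class
#' precision 0 with a warning.
#'
#' @param confusion predicted x true confusion matrix.
#' @return list with `precision`, `recall`, `f1` and the per-class values
#'   (`perClass`, a data.frame).
#' @export
weightedMetrics <- function(confusion) {
  m <- as.matrix(confusion)
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix")
  trueCounts <- colSums(m)
  predCounts <- rowSums(m)
  correct <- diag(m)
  if (any(predCounts == 0 & trueCounts > 0))
    warning("class(es) never predicted; their precision is set to 0")
  precision <- ifelse(predCounts > 0, correct / predCounts, 0)
  recall <- ifelse(trueCounts > 0, correct / trueCounts, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- trueCounts / n
  list(precision = sum(w * precision),
       recall = sum(w * recall),
       f1 = sum(w * f1),
       perClass = data.frame(class = colnames(m) %||% seq_along(correct),
                             precision = precision, recall = recall,
                             f1 = f1, support = trueCounts))
}

#' One-vs-all ROC curves and AUCs
#'
#' For each class, the ROC of that class's predicted probability against the
#' binarised truth, with tied probabilities grouped at a single threshold
#' and the AUC computed by the trapezoid rule. A class absent from `yTrue`
#' has no defined ROC and reports `NA`.
#'
#' @param probabilities `n x C` matrix of class probabilities (rows sum
#'   to 1); columns follow `classes`.
#' @param yTrue true class labels.
#' @param classes class set matching the probability columns.
#' @return named list per class: `curve` (data.frame `threshold`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
rocOneVsAll <- function(probabilities, yTrue, classes = NULL) {
  probabilities <- rbind(probabilities)
  classes <- classes %||% sort(unique(yTrue))
  if (ncol(probabilities) != length(classes))
    stop("probability columns must match the class set")
  rs <- rowSums(probabilities)
  if (any(abs(rs - 1) > 1e-6))
    stop("probability rows must sum to 1")
  out <- lapply(seq_along(classes), function(ci) {
    pos <- yTrue == classes[ci]
    if (!any(pos))
      return(list(curve = NULL, auc = NA_real_))
    p <- probabilities[, ci]
    thr <- c(Inf, sort(unique(p), decreasing = TRUE))
    nPos <- sum(pos); nNeg <- sum(!pos)
    tpr <- vapply(thr, function(t) sum(p >= t & pos) / nPos, numeric(1))
    fpr <- if (nNeg > 0)
      vapply(thr, function(t) sum(p >= t & !pos) / nNeg, numeric(1))
    else rep(0, length(thr))
    auc <- if (nNeg > 0)
      sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    else NA_real_
    list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
         auc = auc)
  })
  names(out) <- as.character(classes)
  out
}

#' Full evaluation report
#'
#' Builds a [MetricsReport-class] from truth and predictions: confusion
#' matrix (predicted x true), balanced accuracy, support-weighted
#' precision/recall/F1 and, when probabilities are supplied, per-class
#' one-vs-all AUCs.
#'
#' @param yTrue,yPred label vectors.
#' @param probabilities optional `n x C` probability matrix for the ROC.
#' @param classes class set.
#' @return a [MetricsReport-class].
#' @export
evaluatePredictions <- function(yTrue, yPred, probabilities = NULL,
                                classes = NULL) {
  classes <- classes %||% sort(unique(c(yTrue, yPred)))
  conf <- confusionMatrix(yTrue, yPred, classes)
  wm <- weightedMetrics(conf)
  auc <- if (!is.null(probabilities)) {
    roc <- rocOneVsAll(probabilities, yTrue, classes)
    stats::setNames(vapply(roc, `[[`, numeric(1), "auc"),
                    as.character(classes))
  } else stats::setNames(numeric(0), character(0))
  new("MetricsReport", confusion = unclass(conf),
      balancedAccuracy = balancedAccuracy(conf),
      weightedPrecision = wm$precision,
      weightedRecall = wm$recall,
      weightedF1 = wm$f1,
      perClassAUC = auc)
}

#' Collapse a score-by-status cross-tabulation to a status confusion matrix
#'
#' Takes a predicted-status x true-group table whose true columns are IHC
#' score groups (`0`, `1`, `2-`, `2+`, `3`, any subset) and collapses the
#' columns to true HER2 status using the score-to-status rule (`0`, `1`,
#' `2-` negative; `2+`, `3` positive).
#'
#' @param crossTab 2 x K matrix, rows `Negative`, `Positive` (predicted),
#'   columns named by score group.
#' @return 2 x 2 status confusion matrix (predicted x true).
#' @export
collapseScoreCrossTab <- function(crossTab) {
  stopifnot(nrow(crossTab) == 2L)
  groups <- colnames(crossTab)
  if (is.null(groups)) stop("crossTab needs score-group column names")
  negGroups <- c("0", "1", "2-")
  posGroups <- c("2+", "3")
  if (!all(groups %in% c(negGroups, posGroups)))
    stop("unknown score group(s): ",
         paste(setdiff(groups, c(negGroups, posGroups)), collapse = ", "))
  m <- cbind(
    Negative = rowSums(crossTab[, groups %in% negGroups, drop = FALSE]),
    Positive = rowSums(crossTab[, groups %in% posGroups, drop = FALSE]))
  rownames(m) <- c("Negative", "Positive")
  m
}
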