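#' Staining-intensity slide descriptor
#'
#' The single-feature comparator to the MIL classifier: the descriptor of a
#' spot is `d_max`, the maximum over its tiles of the mean DAB concentration
#' ([meanTileDAB()]) — a max-aggregated multiple-instance formulation where
#' each instance's feature is its average staining intensity.
#'
#' @param bag a [TileBag-class].
#' @param profile a [StainProfile-class].
#' @return numeric scalar `d_max` (named by spot id).
#' @export
slideDescriptor <- function(bag, profile = rjHDABProfile()) {
  stopifnot(is(bag, "TileBag"))
  if (nTiles(bag) == 0L)
    stop(sprintf("empty bag for spot '%s'", spotId(bag)))
  means <- vapply(bag@tiles, meanTileDAB, numeric(1), profile = profile)
  stats::setNames(max(means), spotId(bag))
}

#' Descriptors for a whole cohort
#'
#' @param images list of [SpotImage-class] objects (or of
#'   [TileBag-class] bags).
#' @param tileSize tile side used when tiling images (desk default 32).
#' @param profile a [StainProfile-class].
#' @param discardEmpty drop background tiles before the maximum?
#' @return data.frame with columns `spot_id`, `d_max`.
#' @export
cohortDescriptors <- function(images, tileSize = 32L,
                              profile = rjHDABProfile(),
                              discardEmpty = TRUE) {
  rows <- lapply(images, function(x) {
    bag <- if (is(x, "TileBag")) x
    else tileImage(x, tileSize = tileSize, discardEmpty = discardEmpty)
    data.frame(spot_id = spotId(bag),
               d_max = unname(slideDescriptor(bag, profile)))
  })
  do.call(rbind, rows)
}

# penalised multinomial logistic regression on a single feature, fitted by
# maximum likelihood with stats::optim (glmnet requires >= 2 predictors, so
# the 1-D model is fitted directly; L2 penalty for numerical stability)
softmaxFit1d <- function(x, y, classes, lambda = 1e-4) {
  C <- length(classes)
  yi <- match(y, classes)
  nll <- function(theta) {
    b <- c(0, theta[seq_len(C - 1)])          # class 1 is the reference
    a <- c(0, theta[C:(2 * C - 2)])
    logits <- outer(x, b) + matrix(a, length(x), C, byrow = TRUE)
    logits <- logits - apply(logits, 1, max)
    p <- exp(logits) / rowSums(exp(logits))
    -sum(log(pmax(p[cbind(seq_along(x), yi)], 1e-12))) +
      lambda * sum(theta^2) / 2
  }
  fit <- stats::optim(rep(0, 2 * (C - 1)), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(slope = c(0, fit$par[seq_len(C - 1)]),
       intercept = c(0, fit$par[C:(2 * C - 2)]),
       classes = classes, lambda = lambda)
}

#' Fit the staining-intensity logistic classifier
#'
#' One-dimensional-input logistic regression on the slide descriptor
#' `d_max`: binary for the HER2 status task, multinomial for the IHC score
#' task. The fit is penalised maximum likelihood with a fixed small L2
#' penalty for numerical stability (the penalty is a configuration key).
#'
#' @param descriptors data.frame from [cohortDescriptors()] (columns
#'   `spot_id`, `d_max`), or a numeric vector of descriptors.
#' @param labels labels data.frame (`spot_id`, `ihc_score`, `her2_status`),
#'   or a label vector aligned with a numeric `descriptors`.
#' @param task `"status"` or `"score"`.
#' @param lambda L2 penalty (default 1e-4).
#' @return an object of class `intensityClassifier`.
#' @export
fitIntensityClassifier <- function(descriptors, labels,
                                   task = c("status", "score"),
                                   lambda = 1e-4) {
  task <- match.arg(task)
  if (is.data.frame(descriptors)) {
    labels <- labels[match(descriptors$spot_id, labels$spot_id), ,
                     drop = FALSE]
    x <- descriptors$d_max
    y <- if (task == "status") labels$her2_status else labels$ihc_score
  } else {
    x <- as.numeric(descriptors)
    y <- labels
  }
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stop("need at least two classes to fit the intensity classifier")
  fit <- softmaxFit1d(x, y, classes, lambda)
  structure(list(fit = fit, task = task, classes = classes,
                 lambda = lambda),
            class = "intensityClassifier")
}

#' Predict from the intensity classifier
#'
#' @param object an `intensityClassifier`.
#' @param newdata numeric vector of `d_max` descriptors (or a data.frame
#'   with a `d_max` column).
#' @param type `"prob"` (default) for the class-probability matrix or
#'   `"class"` for hard labels.
#' @param ... unused.
#' @return probability matrix (`n x C`) or label vector.
#' @export
predict.intensityClassifier <- function(object, newdata,
                                        type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- if (is.data.frame(newdata)) newdata$d_max else as.numeric(newdata)
  f <- object$fit
  logits <- outer(x, f$slope) +
    matrix(f$intercept, length(x), length(f$classes), byrow = TRUE)
  logits <- logits - apply(logits, 1, max)
  p <- exp(logits) / rowSums(exp(logits))
  colnames(p) <- as.character(f$classes)
  if (type == "prob") p else f$classes[max.col(p, ties.method = "first")]
}

#' @export
print.intensityClassifier <- function(x, ...) {
  cat(sprintf(
    "intensity baseline (%s task): 1-D logistic regression on d_max, %d classes, L2 penalty %g\n",
    x$task, length(x$classes), x$lambda))
  invisible(x)
}
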