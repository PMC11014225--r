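#' @include AllClasses.R
NULL

# round half away from zero to 1 decimal (the convention that reproduces
# diagnostic tables reported to one decimal)
.round1 <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

.ratioPct <- function(num, den) if (den == 0) NA_real_ else .round1(100 * num / den)

.emptyMetrics <- function() {
  new("ConfusionMetrics", tp = 0L, fp = 0L, tn = 0L, fn = 0L,
      sensitivity = NA_real_, specificity = NA_real_, ppv = NA_real_,
      npv = NA_real_, accuracy = NA_real_)
}

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity `100 tp/(tp+fn)`, specificity `100 tn/(tn+fp)`, positive
#' predictive value `100 tp/(tp+fp)`, negative predictive value
#' `100 tn/(tn+fn)` and accuracy `100 (tp+tn)/n`, as percentages rounded
#' half-away-from-zero to one decimal. A ratio with a zero denominator is
#' `NA`, never 0.
#'
#' @param tp,fp,tn,fn non-negative integer counts; their sum must be
#'   positive.
#' @return a [ConfusionMetrics-class].
#' @examples
#' confusionMetrics(tp = 34, fp = 4, tn = 28, fn = 2)  # accuracy 91.2
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("at least one count must be positive")
  new("ConfusionMetrics", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn),
      sensitivity = .ratioPct(tp, tp + fn),
      specificity = .ratioPct(tn, tn + fp),
      ppv = .ratioPct(tp, tp + fp), npv = .ratioPct(tn, tn + fn),
      accuracy = .ratioPct(tp + tn, n))
}

.metricsFromLabels <- function(truth, pred, positive) {
  if (!length(truth)) return(.emptyMetrics())
  confusionMetrics(tp = sum(truth == positive & pred == positive),
                   fp = sum(truth != positive & pred == positive),
                   tn = sum(truth != positive & pred != positive),
                   fn = sum(truth == positive & pred != positive))
}

#' Principal-component projection
#'
#' Fits principal components by eigendecomposition of the covariance of
#' the fit rows (centered on the fit-row means) and projects all rows.
#' Loadings are orthonormal; the sign convention makes the
#' largest-magnitude entry of each loading positive; explained-variance
#' fractions sum to 1 over all components.
#'
#' @param x numeric matrix, samples in rows (at least 2 columns).
#' @param fitRows indices (or logical mask) of the rows the components
#'   are fitted on; default all rows.
#' @return list: `scores` (all rows projected), `loadings` (columns are
#'   components), `explained` (variance fractions).
#' @export
pcaProject <- function(x, fitRows = NULL) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 columns")
  if (is.null(fitRows)) fitRows <- seq_len(nrow(x))
  xf <- x[fitRows, , drop = FALSE]
  if (nrow(xf) < 2) stop("need at least 2 fit rows")
  ctr <- colMeans(xf)
  C <- stats::cov(xf)
  if (all(abs(C) < .Machine$double.eps)) stop("zero-variance panel")
  ee <- eigen(C, symmetric = TRUE)
  V <- ee$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  ev <- pmax(ee$values, 0)
  scores <- sweep(x, 2, ctr) %*% V
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(ncol(V)))
  list(scores = scores, loadings = V, explained = ev / sum(ev))
}

#' Evaluate a biomarker panel on the train/test split
#'
#' Fits the shrunken LDA on the training rows restricted to the panel
#' features, predicts every sample, and reports confusion metrics for
#' the training, testing and combined sets (combined counts are the
#' cell-wise sums), together with principal-component scores of the
#' panel (components fitted on the training rows and applied to all
#' rows; set `refitPCA = TRUE` to fit on all rows instead).
#'
#' @param fs a [BreathFeatureSet-class] whose `colData` carries `group`
#'   and `role`.
#' @param panel feature indices or feature names of the panel.
#' @param shrinkage LDA covariance shrinkage (default 0.1).
#' @param positive positive class (default `"CRC"`).
#' @param refitPCA fit the principal components on all rows rather than
#'   the training rows only.
#' @return an [EvaluationReport-class].
#' @export
evaluatePanel <- function(fs, panel, shrinkage = 0.1, positive = "CRC",
                          refitPCA = FALSE) {
  stopifnot(is(fs, "BreathFeatureSet"))
  X <- featureValues(fs)
  if (is.character(panel)) {
    panelIdx <- match(panel, colnames(X))
    if (anyNA(panelIdx)) stop("panel feature(s) not found: ",
                              paste(panel[is.na(panelIdx)], collapse = ", "))
  } else panelIdx <- as.integer(panel)
  if (any(panelIdx < 1 | panelIdx > ncol(X))) stop("panel index out of range")
  cd <- colData(fs)
  group <- as.character(cd$group)
  role <- as.character(cd$role)
  trainRows <- which(role == "train")
  testRows <- which(role == "test")
  if (!length(trainRows)) stop("no training rows")
  if (!length(testRows)) warning("empty test set; training-only report")

  Xp <- X[, panelIdx, drop = FALSE]
  model <- fitLDA(Xp[trainRows, , drop = FALSE], group[trainRows],
                  positive = positive, shrinkage = shrinkage)
  pred <- predictLDA(model, Xp)
  predictions <- data.frame(sample_id = rownames(X), group = group,
                            role = role, score = pred$score,
                            predicted = pred$label, stringsAsFactors = FALSE)

  mTrain <- .metricsFromLabels(group[trainRows], pred$label[trainRows], positive)
  mTest <- .metricsFromLabels(group[testRows], pred$label[testRows], positive)
  mAll <- .metricsFromLabels(group, pred$label, positive)

  pca <- if (length(panelIdx) >= 2) {
    fitOn <- if (refitPCA) seq_len(nrow(Xp)) else trainRows
    tryCatch(pcaProject(Xp, fitRows = fitOn), error = function(e) list())
  } else list()

  new("EvaluationReport", training = mTrain, testing = mTest, combined = mAll,
      predictions = predictions, panel = colnames(X)[panelIdx], pca = pca,
      model = model)
}

#' @describeIn evaluatePanel metrics of an [EvaluationReport-class] shaped
#'   like a diagnostic summary table (rows: subject number, positive and
#'   negative calls, specificity, sensitivity, predictive values, total
#'   accuracy; columns: training, testing, combined), percentages to one
#'   decimal.
#' @param object an `EvaluationReport`
#' @export
setMethod("metricsTable", "EvaluationReport", function(object) {
  col <- function(m) c(`Subject number` = m@tp + m@fp + m@tn + m@fn,
                       Positive = m@tp + m@fp, Negative = m@tn + m@fn,
                       Specificity = m@specificity, Sensitivity = m@sensitivity,
                       `Positive predictive value` = m@ppv,
                       `Negative predictive value` = m@npv,
                       `Total accuracy` = m@accuracy)
  out <- data.frame(training = col(object@training),
                    testing = col(object@testing),
                    combined = col(object@combined), check.names = FALSE)
  out
})
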