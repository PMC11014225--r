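#' @include AllClasses.R
NULL

.binaryLabels <- function(y, positive = NULL) {
  y <- as.character(y)
  lev <- unique(y)
  if (length(lev) != 2L) stop("exactly two classes required, got ", length(lev))
  if (is.null(positive)) positive <- if ("CRC" %in% lev) "CRC" else lev[1]
  if (!positive %in% lev) stop("positive class '", positive, "' not present")
  list(pos = positive, neg = setdiff(lev, positive), ind = as.integer(y == positive))
}

#' Fit a two-class Fisher linear discriminant
#'
#' Computes the pooled within-class covariance `S` (denominator `n - 2`),
#' shrinks it toward a scaled identity, `S_lam = (1 - lambda) S +
#' lambda (tr(S)/p) I`, and sets the weight vector
#' `w = S_lam^{-1} (mu_pos - mu_neg)` with threshold
#' `w . (mu_pos + mu_neg) / 2` (equal class priors).
#'
#' @param x numeric matrix, samples in rows.
#' @param y class labels (two distinct values).
#' @param positive label of the positive class (default `"CRC"` when
#'   present, else the first label).
#' @param shrinkage covariance shrinkage `lambda` in \[0, 1\] (default 0;
#'   0 reproduces textbook LDA).
#' @return an [LDAModel-class].
#' @export
fitLDA <- function(x, y, positive = NULL, shrinkage = 0) {
  x <- as.matrix(x)
  lab <- .binaryLabels(y, positive)
  if (sum(lab$ind == 1) < 1 || sum(lab$ind == 0) < 1)
    stop("both classes must be present")
  p <- ncol(x)
  mu1 <- colMeans(x[lab$ind == 1, , drop = FALSE])
  mu0 <- colMeans(x[lab$ind == 0, , drop = FALSE])
  c1 <- sweep(x[lab$ind == 1, , drop = FALSE], 2, mu1)
  c0 <- sweep(x[lab$ind == 0, , drop = FALSE], 2, mu0)
  S <- (crossprod(c1) + crossprod(c0)) / (nrow(x) - 2)
  Sl <- (1 - shrinkage) * S + shrinkage * (sum(diag(S)) / p) * diag(p)
  w <- tryCatch(solve(Sl, mu1 - mu0), error = function(e)
    stop("singular pooled covariance; increase shrinkage", call. = FALSE))
  m <- rbind(mu1, mu0)
  rownames(m) <- c(lab$pos, lab$neg)
  new("LDAModel", weights = as.numeric(w),
      threshold = sum(w * (mu1 + mu0)) / 2,
      classes = c(lab$pos, lab$neg), shrinkage = shrinkage, means = m)
}

#' Predict with a fitted LDA model
#'
#' Scores are `w . x`; the positive class is predicted when the score is
#' greater than or equal to the threshold (a score exactly at the
#' boundary is called positive).
#'
#' @param model an [LDAModel-class].
#' @param x numeric matrix (or vector for a single sample) with the same
#'   feature count as the model.
#' @return data.frame with `score` and `label`.
#' @export
predictLDA <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model@weights))
    stop("feature count mismatch: model has ", length(model@weights),
         ", data has ", ncol(x))
  score <- as.numeric(x %*% model@weights)
  data.frame(score = score,
             label = ifelse(score >= model@threshold,
                            model@classes[1], model@classes[2]),
             stringsAsFactors = FALSE)
}

#' @describeIn predictLDA standard `predict` interface
#' @param object an `LDAModel`
#' @param newdata samples to score
#' @param ... ignored
#' @export
setMethod("predict", "LDAModel", function(object, newdata, ...)
  predictLDA(object, newdata))

#' Leave-one-out cross-validated accuracy of LDA
#'
#' For each sample, fits the discriminant on the remaining `n - 1`
#' samples and predicts the held-out one; returns the fraction predicted
#' correctly. Deterministic. If removing a sample empties a class, the
#' fold is predicted by the majority class of the remaining samples, with
#' a warning. This pure-R implementation serves as the reference scorer;
#' [subsetSearch()] uses an equivalent compiled path.
#'
#' @inheritParams fitLDA
#' @return accuracy in \[0, 1\].
#' @export
loocvAccuracy <- function(x, y, shrinkage = 0, positive = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 samples")
  lab <- .binaryLabels(y, positive)
  if (sum(lab$ind == 1) < 2 || sum(lab$ind == 0) < 2)
    stop("each class needs at least 2 members")
  y <- as.character(y)
  correct <- 0L
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2L) {
      warning("fold lost a class; predicting remaining-class majority")
      pred <- names(which.max(table(yi)))
    } else {
      fit <- fitLDA(x[-i, , drop = FALSE], yi, positive = lab$pos,
                    shrinkage = shrinkage)
      pred <- predictLDA(fit, x[i, , drop = FALSE])$label
    }
    if (pred == y[i]) correct <- correct + 1L
  }
  correct / n
}

#' Search for the best discriminant feature subset
#'
#' Scores feature subsets of size `k` by leave-one-out cross-validated
#' LDA accuracy on the supplied (training) samples. `exhaustive` mode
#' scores every one of the `choose(p, k)` subsets. Because LOOCV
#' accuracy on a few dozen samples is quantized in steps of `1/n` and a
#' one-fold difference carries no evidence, subsets within `tieMargin`
#' (default one fold, `1/n`) of the top accuracy are treated as tied and
#' ranked by the far more stable training-set Fisher separation
#' `J = (mu1 - mu0)' S_lam^{-1} (mu1 - mu0)`; exact remaining ties go to
#' the lexicographically smallest feature-index tuple. Below the top
#' band, subsets are ranked by (accuracy, separation). `greedy` mode is
#' forward selection with the same scorer.
#'
#' @param x numeric matrix of training samples, or a
#'   [BreathFeatureSet-class] (its training rows are used).
#' @param y class labels (ignored for a `BreathFeatureSet`).
#' @param k subset size.
#' @param mode `"exhaustive"` or `"greedy"`.
#' @param shrinkage covariance shrinkage (default 0.1, a numerical
#'   safeguard for small-n fits).
#' @param positive positive class label.
#' @param budget maximum number of subsets exhaustive mode may score
#'   (default 1e6).
#' @param tieMargin accuracy margin treated as a tie (default `1/n`,
#'   one cross-validation fold).
#' @return a [SubsetSearchResult-class].
#' @export
subsetSearch <- function(x, y = NULL, k = 3, mode = c("exhaustive", "greedy"),
                         shrinkage = 0.1, positive = NULL, budget = 1e6,
                         tieMargin = NULL) {
  mode <- match.arg(mode)
  if (is(x, "BreathFeatureSet")) {
    tr <- colData(x)$role == "train"
    y <- colData(x)$group[tr]
    x <- featureValues(x)[tr, , drop = FALSE]
  }
  x <- as.matrix(x)
  p <- ncol(x)
  n <- nrow(x)
  if (k < 1 || k > p) stop("k must be between 1 and ncol(x)")
  if (is.null(tieMargin)) tieMargin <- 1 / n
  lab <- .binaryLabels(y, positive)

  if (mode == "exhaustive") {
    nsub <- choose(p, k)
    if (nsub > budget)
      stop(sprintf("exhaustive search over %.3g subsets exceeds the budget of %.3g; use mode = 'greedy'",
                   nsub, budget))
    subsets <- utils::combn(p, k)
    res <- .subset_loocv_cpp(x, lab$ind, subsets - 1L, shrinkage)
    ranking <- data.frame(subset = do.call(paste, c(asplit(subsets, 1), sep = ",")),
                          size = k, accuracy = res$accuracy,
                          separation = res$separation,
                          stringsAsFactors = FALSE)
    ord <- .rankSubsets(ranking$accuracy, ranking$separation, tieMargin)
    ranking <- ranking[ord, , drop = FALSE]
    rownames(ranking) <- NULL
    best <- as.integer(subsets[, ord[1]])
    return(new("SubsetSearchResult", ranking = ranking, best = best,
               mode = mode, nEvaluated = nsub, k = as.integer(k)))
  }

  current <- integer(0)
  rows <- list()
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(p), current)
    subsets <- vapply(cand, function(j) sort(c(current, j)),
                      integer(length(current) + 1L))
    subsets <- matrix(subsets, nrow = length(current) + 1L)
    res <- .subset_loocv_cpp(x, lab$ind, subsets - 1L, shrinkage)
    rows[[step]] <- data.frame(
      subset = do.call(paste, c(asplit(subsets, 1), sep = ",")),
      size = step, accuracy = res$accuracy, separation = res$separation,
      stringsAsFactors = FALSE)
    pick <- .rankSubsets(res$accuracy, res$separation, tieMargin)[1]
    current <- sort(c(current, cand[pick]))
  }
  evaluated <- do.call(rbind, rows)
  final <- evaluated[evaluated$size == k, , drop = FALSE]
  final <- final[.rankSubsets(final$accuracy, final$separation, tieMargin), ,
                 drop = FALSE]
  rownames(final) <- NULL
  new("SubsetSearchResult", ranking = final, best = current, mode = mode,
      nEvaluated = nrow(evaluated), k = as.integer(k))
}

# ordering of evaluated subsets: the top accuracy band (within tieMargin
# of the maximum) is sorted by separation, the rest by (accuracy,
# separation); exact ties resolve to the earliest (lexicographically
# smallest) tuple because the enumeration order is lexicographic and
# order() is stable
.rankSubsets <- function(accuracy, separation, tieMargin) {
  top <- accuracy >= max(accuracy) - tieMargin - 1e-12
  sep <- ifelse(is.na(separation), -Inf, separation)
  order(-top, ifelse(top, -sep, -accuracy), -accuracy, -sep)
}
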