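test_that("confusion metrics satisfy their defining identities", {
  set.seed(7)
  for (r in 1:20) {
    cts <- rpois(4, 8)
    if (sum(cts) == 0) cts[1] <- 1
    m <- confusionMetrics(cts[1], cts[2], cts[3], cts[4])
    r1 <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10
    chk <- function(got, num, den) {
      if (den == 0) expect_true(is.na(got)) else expect_equal(got, r1(100 * num / den))
    }
    chk(m@sensitivity, cts[1], cts[1] + cts[4])
    chk(m@specificity, cts[3], cts[3] + cts[2])
    chk(m@ppv, cts[1], cts[1] + cts[2])
    chk(m@npv, cts[3], cts[3] + cts[4])
    expect_equal(m@accuracy, r1(100 * (cts[1] + cts[3]) / sum(cts)))
  }
})

test_that("degenerate confusion tables are handled explicitly", {
  perfect <- confusionMetrics(tp = 9, fp = 0, tn = 7, fn = 0)
  expect_equal(c(perfect@sensitivity, perfect@specificity, perfect@ppv,
                 perfect@npv, perfect@accuracy), rep(100, 5))
  noNeg <- confusionMetrics(tp = 5, fp = 0, tn = 0, fn = 0)
  expect_true(is.na(noNeg@specificity))
  expect_true(is.na(noNeg@npv))
  expect_error(confusionMetrics(0, 0, 0, 0), "positive")
  expect_error(confusionMetrics(-1, 1, 1, 1), "non-negative")
})

test_that("rounding is half away from zero at one decimal", {
  expect_equal(breathpanel:::.round1(94.45), 94.5)
  expect_equal(breathpanel:::.round1(94.44), 94.4)
  expect_equal(breathpanel:::.round1(87.5), 87.5)
  expect_equal(breathpanel:::.round1(89.4736), 89.5)
})

test_that("panel evaluation reports additive train/test/combined counts", {
  set.seed(15)
  groups <- rep(c("CRC", "HC"), each = 10)
  areas <- matrix(rlnorm(20 * 6), 20, 6)
  areas[groups == "CRC", 2] <- areas[groups == "CRC", 2] * 3
  fs <- featureSetFromAreas(areas, groups)
  evr <- evaluatePanel(fs, c(1, 2, 3), shrinkage = 0.1)
  for (cell in c("tp", "fp", "tn", "fn"))
    expect_equal(slot(evr@combined, cell),
                 slot(evr@training, cell) + slot(evr@testing, cell))
  expect_equal(nrow(evr@predictions), 20L)
  expect_equal(sum(evr@predictions$role == "train"), 10L)
  # PCA scores cover every sample and were fitted on the training rows
  expect_equal(nrow(evr@pca$scores), 20L)
  trainScores <- evr@pca$scores[evr@predictions$role == "train", ]
  expect_equal(colMeans(trainScores), setNames(rep(0, 3), colnames(trainScores)),
               tolerance = 1e-9)
})

test_that("a strongly separated simulated panel classifies almost perfectly", {
  set.seed(16)
  groups <- rep(c("CRC", "HC"), each = 12)
  areas <- matrix(rlnorm(24 * 5, sdlog = 0.5), 24, 5)
  areas[groups == "CRC", 1:3] <- areas[groups == "CRC", 1:3] * exp(3 * 0.5)
  fs <- featureSetFromAreas(areas, groups)
  evr <- evaluatePanel(fs, 1:3, shrinkage = 0.1)
  expect_gte(evr@combined@accuracy, 90)
})

test_that("principal components reproduce known covariance structure", {
  set.seed(17)
  # data confined to one direction
  one <- cbind(rnorm(50), 0, 0)
  p1 <- pcaProject(one)
  expect_equal(p1$explained[1], 1)

  n <- 10000
  X <- cbind(rnorm(n, sd = sqrt(2)), rnorm(n, sd = 1))
  p2 <- pcaProject(X)
  expect_lt(max(abs(p2$explained - c(2 / 3, 1 / 3))), 0.02)
  expect_equal(unname(crossprod(p2$loadings)), diag(2), tolerance = 1e-9)
  expect_equal(unname(colMeans(p2$scores)), c(0, 0), tolerance = 1e-9)
  # score variances equal the covariance eigenvalues
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(unname(apply(p2$scores, 2, var)), ev, tolerance = 1e-9)

  # cross-check against the standard PCA implementation
  pr <- stats::prcomp(X, center = TRUE)
  expect_equal(abs(p2$loadings), abs(pr$rotation), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(p2$explained, pr$sdev^2 / sum(pr$sdev^2), tolerance = 1e-9)

  expect_error(pcaProject(matrix(1, 5, 2)), "zero-variance")
  expect_error(pcaProject(matrix(rnorm(10), ncol = 1)), "2 columns")
})

test_that("held-out rows are projected with train-fitted components", {
  set.seed(18)
  X <- matrix(rnorm(40 * 3), 40, 3)
  fit <- pcaProject(X, fitRows = 1:20)
  refit <- pcaProject(X[1:20, ])
  expect_equal(fit$loadings, refit$loadings)
  expect_equal(fit$scores[1:20, ], refit$scores)
  expect_equal(nrow(fit$scores), 40L)
})

test_that("the metrics table carries the one-decimal diagnostic summary", {
  set.seed(19)
  groups <- rep(c("CRC", "HC"), each = 8)
  areas <- matrix(rlnorm(16 * 4), 16, 4)
  areas[groups == "CRC", 1] <- areas[groups == "CRC", 1] * 5
  fs <- featureSetFromAreas(areas, groups)
  evr <- evaluatePanel(fs, c(1, 2), shrinkage = 0.1)
  tab <- metricsTable(evr)
  expect_identical(colnames(tab), c("training", "testing", "combined"))
  expect_equal(tab["Subject number", "combined"], 16)
  expect_equal(tab["Total accuracy", "combined"], evr@combined@accuracy)
})
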