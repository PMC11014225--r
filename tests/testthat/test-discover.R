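test_that("the 1-D discriminant puts the threshold at the class midpoint", {
  x <- matrix(c(1.5, 2.5, -0.5, 0.5), ncol = 1)
  y <- c("CRC", "CRC", "HC", "HC")
  fit <- fitLDA(x, y)
  expect_gt(fit@weights, 0)
  expect_equal(fit@threshold / fit@weights, 1)
})

test_that("the fitted direction matches the closed-form Fisher direction", {
  set.seed(101)
  n <- 10000
  Sigma <- matrix(c(2, 0.8, 0.8, 1), 2)
  L <- chol(Sigma)
  dmu <- c(1, 0.5)
  X <- matrix(rnorm(2 * n), n, 2) %*% L
  y <- rep(c("CRC", "HC"), each = n / 2)
  X[y == "CRC", ] <- sweep(X[y == "CRC", ], 2, dmu, "+")
  fit <- fitLDA(X, y, shrinkage = 0)
  wTrue <- solve(Sigma, dmu)
  ang <- function(a, b) acos(min(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
  expect_lt(ang(fit@weights, wTrue), 2)

  # independent oracle: MASS's discriminant scaling is collinear
  ml <- MASS::lda(X, grouping = y)
  expect_lt(ang(fit@weights, ml$scaling[, 1]), 1)
})

test_that("prediction follows the documented threshold and tie rule", {
  x <- matrix(c(2, 0, 2.2, -0.2), ncol = 1)
  fit <- fitLDA(matrix(c(1.5, 2.5, -0.5, 0.5), ncol = 1), c("CRC", "CRC", "HC", "HC"))
  expect_equal(predictLDA(fit, fit@means)$label, fit@classes)
  atBoundary <- fit@threshold / fit@weights
  expect_equal(predictLDA(fit, matrix(atBoundary))$label, "CRC")
  expect_error(predictLDA(fit, matrix(1, 1, 3)), "mismatch")
  expect_error(fitLDA(matrix(1:4, ncol = 1), rep("CRC", 4)), "two classes")
})

test_that("LOOCV accuracy behaves at its analytic extremes", {
  xsep <- matrix(c(10, 11, 12, -10, -11, -12), ncol = 1)
  ysep <- rep(c("CRC", "HC"), each = 3)
  expect_equal(loocvAccuracy(xsep, ysep), 1.0)

  xor <- matrix(c(0, 1, 0, 1, 0, 0, 1, 1), ncol = 2)
  expect_lte(loocvAccuracy(xor, c("CRC", "HC", "HC", "CRC"), shrinkage = 0.2), 0.5)

  set.seed(33)
  xnull <- matrix(rnorm(40), 20, 2)
  ynull <- rep(c("CRC", "HC"), 10)
  expect_gte(loocvAccuracy(xnull, ynull), 0.3 - 1e-9)
  expect_lte(loocvAccuracy(xnull, ynull), 0.7 + 1e-9)
})

test_that("label-permutation null accuracy centres on chance", {
  set.seed(55)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- rep(c("CRC", "HC"), 15)
  accs <- replicate(60, loocvAccuracy(X, sample(y), shrinkage = 0.1))
  expect_gte(mean(accs), 0.4)
  expect_lte(mean(accs), 0.6)
})

test_that("scale invariance: rescaling a feature leaves unshrunk LOOCV unchanged", {
  set.seed(77)
  X <- matrix(rnorm(24 * 3), 24, 3)
  y <- rep(c("CRC", "HC"), each = 12)
  X[y == "CRC", 1] <- X[y == "CRC", 1] + 1
  a0 <- loocvAccuracy(X, y, shrinkage = 0)
  for (c in c(0.001, 5, 1000)) {
    Xs <- X; Xs[, 1] <- c * Xs[, 1]
    expect_equal(loocvAccuracy(Xs, y, shrinkage = 0), a0)
  }
})

test_that("the exhaustive search matches a brute-force reference for small p", {
  set.seed(88)
  n <- 16; p <- 6; k <- 2
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c("CRC", "HC"), each = n / 2)
  X[y == "CRC", 2] <- X[y == "CRC", 2] + 1.5
  sr <- subsetSearch(X, y, k = k, shrinkage = 0.1)
  expect_equal(sr@nEvaluated, choose(p, k))

  # independent reference: R scorer over an explicit enumeration plus the
  # same documented near-tie selection rule
  subs <- utils::combn(p, k)
  acc <- apply(subs, 2, function(s) loocvAccuracy(X[, s], y, shrinkage = 0.1))
  J <- apply(subs, 2, function(s) {
    fit <- fitLDA(X[, s], y, shrinkage = 0.1)
    sum(fit@weights * (fit@means[1, ] - fit@means[2, ]))
  })
  top <- acc >= max(acc) - 1 / n - 1e-12
  ref <- which(top)[which.max(J[top])]
  expect_equal(bestSubset(sr), subs[, ref])

  rk <- subsetRanking(sr)
  lookup <- match(rk$subset, apply(subs, 2, paste, collapse = ","))
  expect_equal(rk$accuracy, acc[lookup], tolerance = 1e-12)
  expect_equal(rk$separation, J[lookup], tolerance = 1e-9)
})

test_that("greedy search never beats the exhaustive optimum and both are deterministic", {
  set.seed(90)
  X <- matrix(rnorm(20 * 7), 20, 7)
  y <- rep(c("CRC", "HC"), each = 10)
  X[y == "CRC", c(1, 5)] <- X[y == "CRC", c(1, 5)] + 1.2
  ex <- subsetSearch(X, y, k = 3, shrinkage = 0.1)
  gr <- subsetSearch(X, y, k = 3, mode = "greedy", shrinkage = 0.1)
  expect_lte(subsetRanking(gr)$accuracy[1], subsetRanking(ex)$accuracy[1] + 1e-12)
  expect_identical(subsetRanking(ex), subsetRanking(subsetSearch(X, y, k = 3, shrinkage = 0.1)))
  expect_equal(gr@nEvaluated, 7 + 6 + 5)
})

test_that("a single informative feature is found by k = 1 search", {
  set.seed(91)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- rep(c("CRC", "HC"), each = 15)
  X[y == "CRC", 7] <- X[y == "CRC", 7] + 2.5
  expect_equal(bestSubset(subsetSearch(X, y, k = 1, shrinkage = 0.1)), 7L)
})

test_that("planted biomarkers dominate the search among 20 candidates", {
  set.seed(92)
  hits <- integer(10)
  for (r in 1:10) {
    X <- matrix(rnorm(36 * 20), 36, 20)
    y <- rep(c("CRC", "HC"), each = 18)
    X[y == "CRC", 1:3] <- X[y == "CRC", 1:3] + 2.5
    hits[r] <- sum(bestSubset(subsetSearch(X, y, k = 3, shrinkage = 0.1)) %in% 1:3)
  }
  expect_true(all(hits >= 2))
  expect_gte(mean(hits == 3), 0.4)
})

test_that("the exhaustive budget guard points at greedy mode", {
  X <- matrix(rnorm(12 * 30), 12, 30)
  y <- rep(c("CRC", "HC"), each = 6)
  expect_error(subsetSearch(X, y, k = 5, budget = 1000), "greedy")
})
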