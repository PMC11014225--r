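test_that("a noise-free Gaussian is detected with its closed-form area", {
  t <- seq(0, 60, by = 0.1)
  h <- 2; s <- 1.5; mu <- 30
  ch <- directChrom(h * exp(-(t - mu)^2 / (2 * s^2)))
  pk <- detectPeaks(ch)
  expect_equal(nrow(pk), 1L)
  expect_lte(abs(pk$apex_time - mu), 0.1 + 1e-9)
  expect_lt(abs(pk$area - h * s * sqrt(2 * pi)) / (h * s * sqrt(2 * pi)), 0.01)
})

test_that("two well-separated Gaussians give exactly two peaks", {
  t <- seq(0, 80, by = 0.1)
  s <- 2
  y <- exp(-(t - 30)^2 / (2 * s^2)) + exp(-(t - 42)^2 / (2 * s^2))
  pk <- detectPeaks(directChrom(y))
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$apex_time, c(30, 42), tolerance = 0.2)
})

test_that("a flat trace yields no peaks and a stage check guards input", {
  pk <- detectPeaks(directChrom(rep(0, 500)))
  expect_equal(nrow(pk), 0L)
  raw <- directChrom(rep(0, 500), stage = "raw")
  expect_error(detectPeaks(raw), "baseline-corrected")
})

test_that("peak integration follows the trapezoid rule", {
  t <- seq(0, 50, by = 0.1)
  y <- as.numeric(t >= 20 & t <= 30)
  ch <- directChrom(y)
  expect_equal(integratePeak(ch, 20, 30), 10, tolerance = 1e-9)
  expect_equal(integratePeak(directChrom(rep(0, 501)), 10, 20), 0)
  expect_error(integratePeak(ch, -5, 30), "bounds")
  expect_error(integratePeak(ch, 45, 60), "bounds")
})

test_that("identical peak lists align to one feature per peak with zero shifts", {
  pl <- data.frame(apex_time = c(10, 25, 40), apex_height = 1,
                   area = c(2, 3, 4), left = c(8, 23, 38),
                   right = c(12, 27, 42), prominence = 1)
  al <- alignSamples(list(A = pl, B = pl, C = pl))
  expect_equal(nrow(al$features), 3L)
  expect_equal(al$features$rt, c(10, 25, 40))
  expect_true(all(al$shifts == 0))
  expect_true(all(!is.na(al$areas)))
  expect_equal(unname(al$areas[, 2]), rep(3, 3))
})

test_that("a constant retention shift is absorbed by anchor alignment", {
  pl <- data.frame(apex_time = c(10, 25, 40, 60), apex_height = 1,
                   area = 1:4, left = 0, right = 0, prominence = 1)
  shifted <- pl; shifted$apex_time <- pl$apex_time + 2
  base <- alignSamples(list(A = pl, B = pl, C = pl, D = pl),
                       anchorRTs = c(10, 60))
  mixed <- alignSamples(list(A = pl, B = shifted, C = pl, D = shifted),
                        anchorRTs = c(10, 60))
  expect_equal(nrow(mixed$features), nrow(base$features))
  expect_equal(unname(mixed$shifts), c(0, 2, 0, 2))
})

test_that("alignment is invariant to sample order", {
  set.seed(42)
  pls <- lapply(1:5, function(i) {
    n <- 4
    data.frame(apex_time = sort(c(10, 30, 50, 70) + rnorm(n, 0, 0.3)),
               apex_height = 1, area = runif(n), left = 0, right = 0,
               prominence = 1)
  })
  names(pls) <- paste0("S", 1:5)
  a1 <- alignSamples(pls)
  perm <- c(3, 1, 5, 2, 4)
  a2 <- alignSamples(pls[perm])
  expect_equal(a1$features$rt, a2$features$rt, tolerance = 1e-12)
  expect_equal(a1$areas[names(pls), ], a2$areas[names(pls), ])
})

test_that("library matching is one-to-one with verbatim breath annotations", {
  lib <- defaultCompoundLibrary()
  expect_equal(nrow(libraryRecords(lib)), 61L)
  ann <- matchLibrary(c(197, 470), lib)
  expect_equal(ann, c("2,4-dimethylhexane", "Hexane, 2,2,5,5-tetramethyl-"))
  expect_length(matchLibrary(numeric(0), lib), 0L)

  # the compound listed at two RTs carries a qualifier
  expect_equal(matchLibrary(341, lib), "Heptane, 2,5-dimethyl- @341s")
  expect_equal(matchLibrary(239, lib), "Heptane, 2,5-dimethyl- @239s")

  # one library row annotates at most one feature; the closest wins
  two <- matchLibrary(c(196.2, 197.3), lib)
  expect_equal(two[2], "2,4-dimethylhexane")
  expect_true(is.na(two[1]) || two[1] != "2,4-dimethylhexane")
})

test_that("the abundance transform is train-fitted, log-linear and leak-free", {
  set.seed(5)
  groups <- rep(c("CRC", "HC"), each = 6)
  areas <- matrix(rlnorm(12 * 8), 12, 8)
  areas[sample(length(areas), 10)] <- NA
  fs <- featureSetFromAreas(areas, groups)
  expect_s4_class(fs, "BreathFeatureSet")
  V <- featureValues(fs)
  expect_false(anyNA(V))
  tr <- trainSamples(fs)
  expect_equal(colMeans(V[tr, ]), setNames(rep(0, ncol(V)), colnames(V)),
               tolerance = 1e-12)

  # doubling all areas shifts the log by a constant absorbed in centering
  fs2 <- featureSetFromAreas(2 * areas, groups)
  expect_equal(featureValues(fs2), V, tolerance = 1e-9)
  expect_equal(transformDescriptor(fs2)$center - transformDescriptor(fs)$center,
               setNames(rep(log10(2), ncol(V)), colnames(V)), tolerance = 1e-9)

  # shuffling test-row areas must leave training-row values untouched
  testRows <- setdiff(rownames(areas), tr)
  shuffled <- areas
  shuffled[testRows, ] <- shuffled[sample(testRows), ]
  fs3 <- featureSetFromAreas(shuffled, groups)
  expect_equal(featureValues(fs3)[tr, ], V[tr, ], tolerance = 1e-12)
})

test_that("features with no training variance are dropped with a warning", {
  set.seed(6)
  groups <- rep(c("CRC", "HC"), each = 4)
  areas <- matrix(rlnorm(8 * 4), 8, 4)
  areas[, 2] <- 7   # constant across every sample
  expect_warning(fs <- featureSetFromAreas(areas, groups), "zero training variance")
  expect_equal(nrow(fs), 3L)
})
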