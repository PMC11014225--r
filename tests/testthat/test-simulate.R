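test_that("a noise-free single peak integrates to its recorded true area", {
  cfg <- cleanSingleCfg(rt = 50, duration = 100)
  set.seed(11)
  sim <- simulateChromatogram(cfg, "HC", "S1")
  tr <- sim$truth
  expect_equal(nrow(tr), 1L)
  expect_true(tr$included)
  total <- pracma::trapz(rtime(sim$chromatogram), intensity(sim$chromatogram))
  expect_lt(abs(total - tr$true_area) / tr$true_area, 0.001)
  # apex recorded at the trace maximum
  tmax <- rtime(sim$chromatogram)[which.max(intensity(sim$chromatogram))]
  expect_equal(tr$true_apex, tmax)
})

test_that("simulated biomarker group shift matches the generative model", {
  cfg <- smallCfg(effectSize = 1.5, ampLogSD = 0.5)
  set.seed(21)
  compounds <- breathpanel:::.compoundTable(cfg)
  nrep <- 250
  logA <- function(group) replicate(nrep, {
    tr <- simulateChromatogram(cfg, group, "S", compounds)$truth
    log(tr$true_area[tr$is_biomarker])
  })
  a1 <- logA("CRC"); a0 <- logA("HC")
  shift <- mean(a1) - mean(a0)
  se <- sqrt(var(a1) / nrep + var(a0) / nrep)
  expect_lt(abs(shift - 1.5 * 0.5), 3 * se)
})

test_that("a zero effect size yields identical biomarker distributions", {
  cfg <- smallCfg(effectSize = 0)
  compounds <- NULL
  nonsig <- 0L
  for (s in 1:20) {
    set.seed(1000 + s)
    if (is.null(compounds)) compounds <- breathpanel:::.compoundTable(cfg)
    a <- replicate(60, log(simulateChromatogram(cfg, "CRC", "S", compounds)$truth$true_area[3]))
    b <- replicate(60, log(simulateChromatogram(cfg, "HC", "S", compounds)$truth$true_area[3]))
    if (stats::wilcox.test(a, b)$p.value > 0.01) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 18L)
})

test_that("cohort simulation is reproducible and respects the study design", {
  cfg <- smallCfg(nCRC = 36, nHC = 32, seed = 5)
  coh1 <- simulateCohort(cfg)
  coh2 <- simulateCohort(cfg)
  expect_identical(lapply(coh1$chromatograms, intensity),
                   lapply(coh2$chromatograms, intensity))
  expect_identical(coh1$manifest, coh2$manifest)

  m <- coh1$manifest
  expect_equal(sum(m$group == "CRC"), 36)
  expect_equal(sum(m$group == "HC"), 32)
  expect_equal(sum(m$role == "train" & m$group == "CRC"), 18)
  expect_equal(sum(m$role == "train" & m$group == "HC"), 18)
  expect_equal(sum(m$role == "test" & m$group == "CRC"), 18)
  expect_equal(sum(m$role == "test" & m$group == "HC"), 14)

  small <- simulateCohort(smallCfg(nCRC = 2, nHC = 2, seed = 1))
  expect_length(small$chromatograms, 4L)
  npts <- 200 * 10 + 1
  expect_true(all(vapply(small$chromatograms,
                         function(ch) length(intensity(ch)) == npts, logical(1))))
})

test_that("every simulated sample has complete ground truth", {
  coh <- simulateCohort(smallCfg(nCRC = 3, nHC = 3, seed = 2))
  ids <- names(coh$chromatograms)
  expect_setequal(unique(coh$truth$peaks$sample_id), ids)
  perSample <- table(coh$truth$peaks$sample_id)
  expect_true(all(perSample == nrow(coh$truth$compounds)))
  expect_true(all(coh$truth$panel$rt %in% coh$truth$compounds$rt))
})

test_that("inject_inadequate corrupts the requested number of samples in verifiable ways", {
  cfg <- smallCfg(nCRC = 16, nHC = 14, seed = 9)
  coh <- simulateCohort(cfg)
  totals0 <- vapply(coh$chromatograms, function(ch)
    pracma::trapz(rtime(ch), pmax(intensity(ch), 0)), numeric(1))

  set.seed(31)
  inj <- injectInadequate(coh$chromatograms, fraction = 10 / 30,
                          anchorRTs = c(42, 60), saturationLevel = 10)
  expect_length(inj$corrupted, 10L)
  untouched <- setdiff(names(coh$chromatograms), inj$corrupted)
  for (id in untouched)
    expect_identical(intensity(inj$samples[[id]]), intensity(coh$chromatograms[[id]]))

  floorVal <- 0.01 * median(totals0)
  for (id in inj$corrupted) {
    ch <- inj$samples[[id]]
    y <- intensity(ch)
    mode <- inj$modes[[id]]
    if (mode == "low_signal") {
      expect_lt(pracma::trapz(rtime(ch), pmax(y, 0)), floorVal)
    } else if (mode == "saturated") {
      expect_gt(mean(y >= 10), 0.05)
    } else {
      rep <- qcAssess(ch, floor = floorVal, ceiling = 10,
                      anchorRTs = c(42, 60), minAnchors = 1)
      expect_match(rep$reasons, "missing_anchors")
    }
  }

  ident <- injectInadequate(coh$chromatograms, fraction = 0)
  expect_identical(ident$samples, coh$chromatograms)
  expect_length(ident$corrupted, 0L)
  expect_error(injectInadequate(coh$chromatograms, fraction = 1), "fraction")
})

test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(nCRC = 0), "positive")
  expect_error(simulationConfig(detectionProbability = 1.2), "detectionProbability")
  expect_error(simulationConfig(duration = 100.05, samplingRate = 10), "integer")
  expect_error(simulationConfig(biomarkerRTs = 199.5,
                                libraryPath = miniLibraryPath(c(42, 90))),
               "not in library")
})
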