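test_that("the smoothing filter reproduces polynomials and damps noise", {
  t <- seq(0, 30, by = 0.1)
  poly <- 2 + 0.5 * t - 0.03 * t^2 + 0.001 * t^3
  ch <- Chromatogram("P1", t, poly, stage = "raw")
  sm <- denoise(ch, window = 21, polyorder = 3)
  expect_equal(intensity(sm), poly, tolerance = 1e-9)
  expect_identical(rtime(sm), t)
  expect_equal(processingStage(sm), "denoised")

  set.seed(4)
  noise <- rnorm(length(t))
  nc <- denoise(Chromatogram("N1", t, noise), window = 21, polyorder = 3)
  expect_lt(var(intensity(nc)), var(noise))

  expect_error(denoise(ch, window = 20), "odd")
  expect_error(denoise(ch, window = 21, polyorder = 21), "polyorder")
  expect_error(denoise(sm), "raw")
})

test_that("smoothing a noisy peak keeps the apex within one sample", {
  t <- seq(0, 60, by = 0.1)
  clean <- 1.0 * emgShape(t, 30, 1, 1.5)
  apexClean <- t[which.max(signal::sgolayfilt(clean, p = 3, n = 21))]
  set.seed(8)
  noisy <- clean + rnorm(length(t), 0, max(clean) / 10)
  sm <- denoise(Chromatogram("S", t, noisy), window = 21, polyorder = 3)
  expect_lte(abs(t[which.max(intensity(sm))] - apexClean), 0.1 + 1e-9)
})

test_that("baseline correction removes drift without touching the grid", {
  t <- seq(0, 100, by = 0.1)
  zero <- denoise(Chromatogram("Z", t, rep(0, length(t))))
  bc0 <- baselineCorrect(zero)
  expect_equal(max(abs(intensity(bc0))), 0, tolerance = 1e-9)

  set.seed(12)
  nsd <- 0.01
  drift <- 0.5 + 0.002 * t + rnorm(length(t), 0, nsd)
  bc <- baselineCorrect(denoise(Chromatogram("D", t, drift)))
  expect_lt(abs(mean(intensity(bc))), 3 * nsd / sqrt(length(t)))
  expect_identical(rtime(bc), t)
  expect_equal(processingStage(bc), "baseline_corrected")

  expect_warning(baselineCorrect(Chromatogram("R", t, drift)), "raw")
  expect_error(baselineCorrect(bc), "already")
})

test_that("baseline correction is nearly idempotent on simulated traces", {
  coh <- simulateCohort(smallCfg(nCRC = 2, nHC = 2, seed = 3))
  ch <- coh$chromatograms[[1]]
  once <- baselineCorrect(denoise(ch))
  relabeled <- Chromatogram(sampleId(once), rtime(once), intensity(once),
                            stage = "denoised")
  twice <- baselineCorrect(relabeled)
  rms <- sqrt(mean(intensity(once)^2))
  expect_lt(sqrt(mean((intensity(twice) - intensity(once))^2)), 0.01 * rms)
})

test_that("recovered areas after correction track the ground truth", {
  coh <- simulateCohort(smallCfg(nCRC = 2, nHC = 2, seed = 6))
  ch <- coh$chromatograms[[1]]
  pk <- detectPeaks(baselineCorrect(denoise(ch)))
  tr <- coh$truth$peaks
  tr <- tr[tr$sample_id == sampleId(ch) & tr$included, ]
  errs <- vapply(seq_len(nrow(tr)), function(i) {
    d <- abs(pk$apex_time - tr$true_apex[i])
    j <- which.min(d)
    if (d[j] <= 3) abs(pk$area[j] - tr$true_area[i]) / tr$true_area[i] else NA_real_
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.05)
})

test_that("quality control flags each corruption mode and nothing else", {
  cfg <- smallCfg(nCRC = 10, nHC = 10, seed = 13)
  coh <- simulateCohort(cfg)
  qc <- cohortQC(coh$chromatograms, ceiling = 10, anchorRTs = c(42, 60),
                 minAnchors = 2)
  expect_true(all(qc$adequate))
  expect_true(all(qc$reasons == ""))

  set.seed(14)
  inj <- injectInadequate(coh$chromatograms, 6 / 20, anchorRTs = c(42, 60),
                          saturationLevel = 10)
  qc2 <- cohortQC(inj$samples, ceiling = 10, anchorRTs = c(42, 60),
                  minAnchors = 2)
  expect_equal(sum(!qc2$adequate), 6)
  expect_setequal(qc2$sample_id[!qc2$adequate], inj$corrupted)
  kept <- suppressMessages(filterInadequate(inj$samples, qc2))
  expect_length(kept, 14L)
  expect_identical(names(kept), setdiff(names(inj$samples), inj$corrupted))
})

test_that("QC thresholds are scale-aware", {
  coh <- simulateCohort(smallCfg(nCRC = 2, nHC = 2, seed = 17))
  ch <- coh$chromatograms[[1]]
  floorVal <- 0.5
  r1 <- qcAssess(ch, floor = floorVal, ceiling = 10, anchorRTs = c(42, 60),
                 minAnchors = 2)
  for (c in c(0.01, 100)) {
    scaled <- Chromatogram(sampleId(ch), rtime(ch), c * intensity(ch))
    r2 <- qcAssess(scaled, floor = c * floorVal, ceiling = c * 10,
                   anchorRTs = c(42, 60), minAnchors = 2)
    expect_identical(r2$adequate, r1$adequate)
    expect_identical(r2$reasons, r1$reasons)
  }
})

test_that("filter_inadequate preserves order and validates its inputs", {
  coh <- simulateCohort(smallCfg(nCRC = 3, nHC = 2, seed = 19))
  qc <- cohortQC(coh$chromatograms, anchorRTs = c(42, 60), minAnchors = 2)
  kept <- filterInadequate(coh$chromatograms, qc)
  expect_identical(names(kept), names(coh$chromatograms))
  expect_error(filterInadequate(coh$chromatograms[1:3], qc), "one-to-one")
  expect_length(filterInadequate(list(), qc[0, ]), 0L)
})
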