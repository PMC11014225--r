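#' @include AllClasses.R
NULL

# robust noise scale of a trace from first differences
.noiseEstimate <- function(y) stats::mad(diff(y)) / sqrt(2)

# robust scale of the lower (peak-free) residual cluster: smoothing
# correlates the point noise, so a derivative-based estimate collapses;
# instead read the spread off low quantiles, which peaks (strictly
# positive excursions) cannot contaminate
.clusterScale <- function(r) {
  (stats::quantile(r, 0.2, names = FALSE) -
     stats::quantile(r, 0.05, names = FALSE)) /
    (stats::qnorm(0.2) - stats::qnorm(0.05))
}

#' Savitzky-Golay de-noising
#'
#' Moving least-squares polynomial smoothing of a raw trace. The filter
#' reproduces any signal that is locally a polynomial of degree up to
#' `polyorder` exactly, and attenuates high-frequency detector noise.
#' Length and time grid are unchanged.
#'
#' @param chrom a raw [Chromatogram-class].
#' @param window odd filter window length in samples (default 21).
#' @param polyorder polynomial order, `0 < polyorder < window` (default 3).
#' @return the smoothed chromatogram, stage `denoised`.
#' @export
denoise <- function(chrom, window = 21, polyorder = 3) {
  if (processingStage(chrom) != "raw")
    stop("denoise expects a raw chromatogram, got stage '",
         processingStage(chrom), "'")
  n <- length(intensity(chrom))
  if (window %% 2 == 0) stop("window must be odd")
  if (window > n) stop("window exceeds trace length")
  if (polyorder <= 0 || polyorder >= window)
    stop("need 0 < polyorder < window")
  sm <- signal::sgolayfilt(intensity(chrom), p = polyorder, n = window)
  Chromatogram(sampleId(chrom), rtime(chrom), sm, stage = "denoised")
}

#' Asymmetric least-squares baseline correction
#'
#' Estimates the slowly varying baseline with a Whittaker smoother under
#' asymmetric weights (points above the running baseline are nearly
#' ignored, points below anchor it), refines it with a second,
#' peak-masked pass (points more than 3 cluster SD above the first-pass
#' baseline, dilated by 2 s, get zero weight; the remaining peak-free
#' points get symmetric unit weight, so the refit is unbiased and
#' bridges smoothly across peaks), recentres so the peak-free residual
#' has median ~ 0, and subtracts. Negative residual intensities are
#' retained, not clipped, so that later peak integration stays unbiased.
#'
#' @param chrom a denoised (or, with a warning, raw) [Chromatogram-class].
#' @param smoothness penalty on the squared second differences of the
#'   baseline (default 1e6); larger values give a stiffer baseline.
#' @param asymmetry weight given to points above the baseline, in
#'   (0, 0.5) (default 0.01).
#' @param maxIter maximum reweighting iterations (default 10); if the
#'   weights have not stabilised by then the last iterate is used and a
#'   warning raised.
#' @return the corrected chromatogram, stage `baseline_corrected`, with
#'   the estimated baseline in `attr(, "baseline")`.
#' @export
baselineCorrect <- function(chrom, smoothness = 1e6, asymmetry = 0.01,
                            maxIter = 10) {
  stage <- processingStage(chrom)
  if (stage == "baseline_corrected")
    stop("chromatogram is already baseline corrected")
  if (stage == "raw")
    warning("baseline-correcting a raw (not de-noised) chromatogram")
  if (smoothness <= 0) stop("smoothness must be positive")
  if (asymmetry <= 0 || asymmetry >= 0.5) stop("asymmetry must be in (0, 0.5)")
  y <- intensity(chrom)
  fit <- .als_baseline_cpp(y, smoothness, asymmetry, as.integer(maxIter))
  if (!fit$converged)
    warning(sprintf("baseline weights not settled after %d iterations (sample %s); using last iterate",
                    maxIter, sampleId(chrom)))
  # second pass: refit symmetrically on peak-free points only
  r1 <- y - fit$baseline
  # mask everything more than 3 cluster-SD above the peak-free residual
  # cluster so peak flanks cannot pull the refit; the scale comes from
  # low quantiles, which strictly positive peak mass cannot contaminate
  nsd1 <- .clusterScale(r1)
  peaky <- r1 > 3 * nsd1
  dil <- max(1L, round(2 / (rtime(chrom)[2] - rtime(chrom)[1])))
  peaky <- as.logical(stats::filter(as.numeric(peaky), rep(1, 2 * dil + 1),
                                    sides = 2) > 0)
  peaky[is.na(peaky)] <- FALSE
  w2 <- as.numeric(!peaky)
  baseline <- if (any(w2 > 0)) .whittaker_cpp(y, w2, smoothness) else fit$baseline
  resid <- y - baseline
  # the asymmetric weights make the fit hug the lower noise envelope,
  # leaving a small positive pedestal; recentre on the center of the
  # peak-free noise cluster (iterated trimmed median started from a low
  # quantile, which always lies in the noise cluster because peak mass
  # is strictly positive), so peak-free regions end up with median ~ 0
  nsd <- .noiseEstimate(resid)
  pedestal <- stats::quantile(resid, 0.2, names = FALSE)
  for (it in 1:5) {
    inCluster <- abs(resid - pedestal) < 5 * nsd
    if (!any(inCluster)) break
    pedestal <- stats::median(resid[inCluster])
  }
  out <- Chromatogram(sampleId(chrom), rtime(chrom), resid - pedestal,
                      stage = "baseline_corrected")
  attr(out, "baseline") <- baseline + pedestal
  out
}

#' Quality-control assessment of one chromatogram
#'
#' Flags technically inadequate runs. A sample is adequate iff all of:
#' total integrated signal (trapezoid of the positive part) at or above
#' `floor`; fraction of points at or above the detector `ceiling` not
#' exceeding `maxSaturation`; at least `minAnchors` of the anchor peaks
#' found (a detected local maximum within `anchorTol` seconds of the
#' anchor retention time). Thresholds are scale-aware: scaling a trace
#' together with `floor` and `ceiling` by the same factor leaves the
#' verdict unchanged. Intended to run on the raw trace, where saturation
#' and total signal are meaningful detector-output properties.
#'
#' @param chrom a [Chromatogram-class].
#' @param floor minimum total signal, detector units times seconds.
#' @param ceiling detector full-scale value, detector units.
#' @param anchorRTs anchor retention times (s).
#' @param minAnchors minimum anchors found (default 3).
#' @param maxSaturation maximum tolerated saturated fraction (default 0.05).
#' @param anchorTol anchor match tolerance in seconds (default 6, covering run-level retention shift plus per-peak jitter).
#' @return one-row data.frame: `sample_id`, `total_signal`,
#'   `saturation_fraction`, `anchor_peaks_found`, `adequate`, `reasons`
#'   (semicolon-joined subset of `low_signal`, `saturated`,
#'   `missing_anchors`; empty string iff adequate).
#' @export
qcAssess <- function(chrom, floor, ceiling, anchorRTs = c(42, 53, 65, 137, 276, 502),
                     minAnchors = 3, maxSaturation = 0.05, anchorTol = 6) {
  y <- intensity(chrom)
  t <- rtime(chrom)
  total <- pracma::trapz(t, pmax(y, 0))
  satFrac <- mean(y >= ceiling)
  noise <- .noiseEstimate(y)
  pk <- .find_peaks_cpp(y, min_prominence = max(10 * noise, 1e-12),
                        min_height = -Inf)
  apexes <- t[pk$index]
  found <- sum(vapply(anchorRTs, function(a)
    length(apexes) > 0 && min(abs(apexes - a)) <= anchorTol, logical(1)))
  reasons <- character(0)
  if (total < floor) reasons <- c(reasons, "low_signal")
  if (satFrac > maxSaturation) reasons <- c(reasons, "saturated")
  if (found < minAnchors) reasons <- c(reasons, "missing_anchors")
  data.frame(sample_id = sampleId(chrom), total_signal = total,
             saturation_fraction = satFrac, anchor_peaks_found = found,
             adequate = length(reasons) == 0L,
             reasons = paste(reasons, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Quality control of a whole cohort
#'
#' Runs [qcAssess()] on every sample, with the total-signal floor derived
#' from the cohort itself: `floorFrac` (default 1\%) of the median total
#' signal across samples.
#'
#' @param samples named list of [Chromatogram-class].
#' @param ceiling detector full-scale value (default 10).
#' @param anchorRTs anchor retention times.
#' @param floorFrac floor as a fraction of the cohort median total signal.
#' @param minAnchors,maxSaturation,anchorTol passed to [qcAssess()].
#' @return data.frame of per-sample QC reports, one row per sample, with
#'   the applied `floor` in `attr(, "floor")`.
#' @export
cohortQC <- function(samples, ceiling = 10, anchorRTs = c(42, 53, 65, 137, 276, 502),
                     floorFrac = 0.01, minAnchors = 3, maxSaturation = 0.05,
                     anchorTol = 6) {
  totals <- vapply(samples, function(ch)
    pracma::trapz(rtime(ch), pmax(intensity(ch), 0)), numeric(1))
  floorVal <- floorFrac * stats::median(totals)
  reports <- do.call(rbind, lapply(samples, qcAssess, floor = floorVal,
    ceiling = ceiling, anchorRTs = anchorRTs, minAnchors = minAnchors,
    maxSaturation = maxSaturation, anchorTol = anchorTol))
  rownames(reports) <- NULL
  attr(reports, "floor") <- floorVal
  reports
}

#' Drop technically inadequate samples
#'
#' Keeps the samples whose QC report says `adequate`, preserving order,
#' and messages each exclusion with its reasons.
#'
#' @param samples named list of [Chromatogram-class].
#' @param reports QC report data.frame from [cohortQC()] / [qcAssess()],
#'   one row per sample.
#' @return the retained sub-list of `samples`.
#' @export
filterInadequate <- function(samples, reports) {
  ids <- vapply(samples, sampleId, character(1))
  if (length(samples) != nrow(reports) || !setequal(ids, reports$sample_id))
    stop("reports do not match samples one-to-one")
  reports <- reports[match(ids, reports$sample_id), , drop = FALSE]
  bad <- !reports$adequate
  for (i in which(bad))
    message(sprintf("excluding %s: %s", ids[i], reports$reasons[i]))
  samples[!bad]
}
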