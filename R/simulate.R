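#' @include AllClasses.R AllGenerics.R
NULL

#' Simulation settings for synthetic breath chromatograms
#'
#' Parameters of the synthetic micro-GC breath cohort generator. Peaks are
#' exponentially modified Gaussians (EMG) placed at compound-library
#' retention times with log-normal areas; a configurable set of biomarker
#' compounds has its mean log-area shifted upward in the cancer (CRC)
#' group by `effectSize` within-group standard deviations. A set of
#' ubiquitous, high-abundance "anchor" compounds (isoprene and common
#' alkanes) is always present and carries a boosted mean log-amplitude;
#' anchors support quality control and retention-time alignment. Because
#' the compound library names 61 peaks while a typical breath run shows
#' on the order of a hundred, `nExtraPeaks` additional unannotated
#' compounds are placed at cohort-level random retention times.
#'
#' @slot nCRC,nHC cohort sizes (defaults 36 and 32).
#' @slot libraryPath path to a compound-library TSV; `""` uses the
#'   packaged breath library.
#' @slot biomarkerRTs retention times (s) of the planted biomarkers
#'   (defaults 197, 341, 470 s).
#' @slot effectSize CRC-vs-HC separation of biomarker mean log-amplitude,
#'   in units of the log-amplitude SD (default 1.5).
#' @slot ampLogMean,ampLogSD mean and SD of log peak area (defaults 0, 0.5).
#' @slot anchorRTs retention times of the always-present anchor compounds.
#' @slot anchorLogBoost added to `ampLogMean` for anchors (default 2).
#' @slot baselineAmplitude baseline drift amplitude in detector units;
#'   `NA` means 5\% of the sample's median apex height.
#' @slot noiseSD detector noise SD; `NA` means 1\% of the sample's median
#'   apex height.
#' @slot rtGlobalJitterSD per-sample global retention-time shift SD, s (default 1).
#' @slot rtPeakJitterSD per-peak retention-time jitter SD, s (default 0.5).
#' @slot peakWidthBaseSD,peakWidthSlope Gaussian width sigma(RT) =
#'   base + slope * RT, s and s/s (defaults 0.8 and 0.001; temperature-programmed GC keeps widths nearly constant across the run).
#' @slot tailingTau EMG exponential tail constant, s (default 1.5).
#' @slot samplingRate detector sampling rate, Hz (default 10).
#' @slot duration run length, s (default 800).
#' @slot detectionProbability probability that a non-anchor, non-biomarker
#'   compound appears in a given sample (default 0.9; biomarkers and
#'   anchors are always present).
#' @slot nExtraPeaks number of unannotated extra compounds (default 40).
#' @slot inadequateFraction fraction of samples corrupted to be
#'   technically inadequate (default 0).
#' @slot saturationLevel detector full-scale value, detector units (default 10).
#' @slot splitMode `"canonical"` (first half of each group by manifest
#'   order trains) or `"random"`.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
  representation(nCRC = "numeric", nHC = "numeric", libraryPath = "character",
    biomarkerRTs = "numeric", effectSize = "numeric", ampLogMean = "numeric",
    ampLogSD = "numeric", anchorRTs = "numeric", anchorLogBoost = "numeric",
    baselineAmplitude = "numeric", noiseSD = "numeric",
    rtGlobalJitterSD = "numeric", rtPeakJitterSD = "numeric",
    peakWidthBaseSD = "numeric", peakWidthSlope = "numeric",
    tailingTau = "numeric", samplingRate = "numeric", duration = "numeric",
    detectionProbability = "numeric", nExtraPeaks = "numeric",
    inadequateFraction = "numeric", saturationLevel = "numeric",
    splitMode = "character", seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  if (object@nCRC < 1 || object@nHC < 1) return("nCRC and nHC must be positive")
  if (object@detectionProbability < 0 || object@detectionProbability > 1)
    return("detectionProbability must be in [0, 1]")
  if (object@inadequateFraction < 0 || object@inadequateFraction >= 1)
    return("inadequateFraction must be in [0, 1)")
  npts <- object@duration * object@samplingRate
  if (abs(npts - round(npts)) > 1e-8)
    return("duration * samplingRate must be an integer number of intervals")
  lib <- .resolveLibrary(object)
  rts <- libraryRecords(lib)$rt_s
  for (b in object@biomarkerRTs)
    if (min(abs(rts - b)) > rtTolerance(lib))
      return(sprintf("biomarker RT %g s not in library within tolerance", b))
  if (!object@splitMode %in% c("canonical", "random"))
    return("splitMode must be 'canonical' or 'random'")
  TRUE
})

#' Create a SimulationConfig
#'
#' @param nCRC,nHC cohort sizes.
#' @param libraryPath compound-library TSV path ("" = packaged library).
#' @param biomarkerRTs biomarker retention times (s).
#' @param effectSize biomarker group separation in log-amplitude SD units.
#' @param ampLogMean,ampLogSD log-area distribution parameters.
#' @param anchorRTs anchor-compound retention times (s).
#' @param anchorLogBoost anchor mean log-amplitude boost.
#' @param baselineAmplitude baseline amplitude (NA = 5\% of median apex height).
#' @param noiseSD noise SD (NA = 1\% of median apex height).
#' @param rtGlobalJitterSD,rtPeakJitterSD retention-time jitter SDs (s).
#' @param peakWidthBaseSD,peakWidthSlope peak width model sigma(RT).
#' @param tailingTau EMG tail constant (s).
#' @param samplingRate sampling rate (Hz).
#' @param duration run length (s).
#' @param detectionProbability per-sample presence probability of minor compounds.
#' @param nExtraPeaks number of unannotated extra compounds.
#' @param inadequateFraction fraction of samples corrupted at cohort level.
#' @param saturationLevel detector full scale.
#' @param splitMode `"canonical"` or `"random"` train/test split.
#' @param seed RNG seed.
#' @return A validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(nCRC = 2, nHC = 2, duration = 100,
#'                         biomarkerRTs = 42, nExtraPeaks = 0)
#' @export
simulationConfig <- function(nCRC = 36, nHC = 32, libraryPath = "",
    biomarkerRTs = c(197, 341, 470), effectSize = 1.5, ampLogMean = 0,
    ampLogSD = 0.5, anchorRTs = c(42, 53, 65, 137, 276, 502),
    anchorLogBoost = 2, baselineAmplitude = NA_real_, noiseSD = NA_real_,
    rtGlobalJitterSD = 1.0, rtPeakJitterSD = 0.5, peakWidthBaseSD = 0.8,
    peakWidthSlope = 0.001, tailingTau = 1.5, samplingRate = 10,
    duration = 800, detectionProbability = 0.9, nExtraPeaks = 40,
    inadequateFraction = 0, saturationLevel = 10,
    splitMode = "canonical", seed = 1) {
  new("SimulationConfig", nCRC = nCRC, nHC = nHC, libraryPath = libraryPath,
      biomarkerRTs = biomarkerRTs, effectSize = effectSize,
      ampLogMean = ampLogMean, ampLogSD = ampLogSD, anchorRTs = anchorRTs,
      anchorLogBoost = anchorLogBoost, baselineAmplitude = baselineAmplitude,
      noiseSD = noiseSD, rtGlobalJitterSD = rtGlobalJitterSD,
      rtPeakJitterSD = rtPeakJitterSD, peakWidthBaseSD = peakWidthBaseSD,
      peakWidthSlope = peakWidthSlope, tailingTau = tailingTau,
      samplingRate = samplingRate, duration = duration,
      detectionProbability = detectionProbability, nExtraPeaks = nExtraPeaks,
      inadequateFraction = inadequateFraction, saturationLevel = saturationLevel,
      splitMode = splitMode, seed = seed)
}

.resolveLibrary <- function(config) {
  if (nzchar(config@libraryPath)) readCompoundLibrary(config@libraryPath)
  else defaultCompoundLibrary()
}

#' Exponentially modified Gaussian peak shape
#'
#' Unit-area EMG density: a Gaussian of width `sigma` convolved with an
#' exponential tail of time constant `tau`. Evaluated in log space for
#' numerical stability far from the apex.
#'
#' @param t times (s).
#' @param mu Gaussian center (s). Note the EMG mode lies slightly later.
#' @param sigma Gaussian width (s).
#' @param tau exponential tail constant (s).
#' @return densities, integrating to 1 over the real line.
#' @export
emgShape <- function(t, mu, sigma, tau) {
  u <- (mu - t + sigma^2 / tau) / (sigma * sqrt(2))
  exp(-log(2 * tau) + (mu - t) / tau + sigma^2 / (2 * tau^2) +
      log(2) + stats::pnorm(u * sqrt(2), lower.tail = FALSE, log.p = TRUE))
}

# Build the per-cohort compound table: library rows plus nExtraPeaks
# unannotated compounds at random RTs (>= minGap from every other RT).
# Draws from the current RNG stream.
.compoundTable <- function(config) {
  lib <- .resolveLibrary(config)
  rec <- libraryRecords(lib)
  tol <- rtTolerance(lib)
  tab <- data.frame(rt = rec$rt_s, name = rec$name,
                    is_library = TRUE, stringsAsFactors = FALSE)
  tab$is_biomarker <- vapply(tab$rt, function(r)
    any(abs(r - config@biomarkerRTs) <= 0.5), logical(1))
  # biomarker designation by nearest library row when not exact
  for (b in config@biomarkerRTs) {
    if (!any(abs(tab$rt - b) <= 0.5)) {
      i <- which.min(abs(tab$rt - b))
      if (abs(tab$rt[i] - b) <= tol) tab$is_biomarker[i] <- TRUE
    }
  }
  tab$is_anchor <- vapply(tab$rt, function(r)
    any(abs(r - config@anchorRTs) <= 0.5), logical(1))
  if (config@nExtraPeaks > 0) {
    extra <- .drawExtraRTs(config@nExtraPeaks, existing = tab$rt,
                           lo = 30, hi = config@duration - 10, minGap = 5)
    tab <- rbind(tab, data.frame(rt = extra,
        name = sprintf("unknown_%04.0f", round(extra)), is_library = FALSE,
        is_biomarker = FALSE, is_anchor = FALSE, stringsAsFactors = FALSE))
  }
  tab <- tab[order(tab$rt), , drop = FALSE]
  rownames(tab) <- NULL
  tab$meanlog <- config@ampLogMean + ifelse(tab$is_anchor, config@anchorLogBoost, 0)
  tab$detect_p <- ifelse(tab$is_anchor | tab$is_biomarker, 1,
                         config@detectionProbability)
  # library RTs are observed apex times, but the EMG mode trails the
  # Gaussian center; pre-compute the mode offset so peaks are emitted
  # with their apex (not their center) at the nominal RT
  sigma <- config@peakWidthBaseSD + config@peakWidthSlope * tab$rt
  tab$mode_offset <- vapply(sigma, function(s)
    stats::optimize(function(u) emgShape(u, 0, s, config@tailingTau),
                    c(-s, s + 4 * config@tailingTau), maximum = TRUE)$maximum,
    numeric(1))
  tab
}

# place n retention times at random, each at least minGap from every
# existing RT and from each other, by sampling without replacement from
# a half-second candidate grid and pruning it as positions are taken
.drawExtraRTs <- function(n, existing, lo, hi, minGap) {
  cand <- seq(lo, hi, by = 0.5)
  cand <- cand[vapply(cand, function(x) min(abs(x - existing)) >= minGap,
                      logical(1))]
  out <- numeric(0)
  for (i in seq_len(n)) {
    if (!length(cand)) stop("could not place extra peaks with the requested gap")
    x <- cand[sample.int(length(cand), 1)] + stats::runif(1, -0.25, 0.25)
    out <- c(out, x)
    cand <- cand[abs(cand - x) >= minGap]
  }
  sort(out)
}

#' Simulate one breath chromatogram
#'
#' Generates a single synthetic micro-GC trace for a CRC or HC subject:
#' baseline drift + the sum of EMG peaks for the compounds present in the
#' sample + Gaussian detector noise. Each peak's apex is its library
#' retention time plus a per-sample global shift and per-peak jitter; each
#' biomarker compound's mean log-area is raised by
#' `effectSize * ampLogSD` in the CRC group. Randomness is taken from the
#' current RNG stream (call `set.seed()` first, or use [simulateCohort()]).
#'
#' @param config a [SimulationConfig-class].
#' @param group `"CRC"` or `"HC"`.
#' @param sampleId sample identifier.
#' @param compounds optional compound table (from a cohort-level draw);
#'   by default built from `config`, drawing any extra-peak retention
#'   times from the current RNG stream.
#' @return list with elements `chromatogram` (a [Chromatogram-class],
#'   stage `raw`) and `truth` (data.frame: one row per compound with the
#'   true area, apex time and apex height of every emitted peak, plus the
#'   sample's global retention-time shift).
#' @export
simulateChromatogram <- function(config, group = c("CRC", "HC"),
                                 sampleId = "S1", compounds = NULL) {
  group <- match.arg(group)
  stopifnot(validObject(config))
  if (is.null(compounds)) compounds <- .compoundTable(config)
  npts <- round(config@duration * config@samplingRate) + 1L
  t <- seq(0, config@duration, length.out = npts)
  nc <- nrow(compounds)

  shift <- stats::rnorm(1, 0, config@rtGlobalJitterSD)
  included <- stats::runif(nc) < compounds$detect_p
  jitter <- stats::rnorm(nc, 0, config@rtPeakJitterSD)
  meanlog <- compounds$meanlog +
    (group == "CRC") * compounds$is_biomarker * config@effectSize * config@ampLogSD
  area <- exp(stats::rnorm(nc, meanlog, config@ampLogSD))

  y <- numeric(npts)
  apex_t <- rep(NA_real_, nc)
  apex_h <- rep(NA_real_, nc)
  dt <- 1 / config@samplingRate
  for (i in seq_len(nc)) {
    if (!included[i]) next
    mu <- compounds$rt[i] - compounds$mode_offset[i] + shift + jitter[i]
    sigma <- config@peakWidthBaseSD + config@peakWidthSlope * compounds$rt[i]
    lo <- max(1L, floor((mu - 8 * sigma) / dt) + 1L)
    hi <- min(npts, ceiling((mu + 8 * sigma + 12 * config@tailingTau) / dt) + 1L)
    if (hi <= lo) next
    win <- lo:hi
    comp <- area[i] * emgShape(t[win], mu, sigma, config@tailingTau)
    y[win] <- y[win] + comp
    j <- which.max(comp)
    apex_t[i] <- t[win][j]
    apex_h[i] <- comp[j]
  }

  medApex <- stats::median(apex_h, na.rm = TRUE)
  if (!is.finite(medApex)) medApex <- 1
  bamp <- if (is.na(config@baselineAmplitude)) 0.05 * medApex else config@baselineAmplitude
  nsd <- if (is.na(config@noiseSD)) 0.01 * medApex else config@noiseSD
  bfreq <- stats::runif(1, 0.5, 1.5)
  bphase <- stats::runif(1, 0, 2 * pi)
  if (bamp > 0) {
    frac <- t / config@duration
    y <- y + bamp * (0.6 + 0.4 * sin(2 * pi * bfreq * frac + bphase) + 0.3 * frac)
  }
  noise <- stats::rnorm(npts, 0, nsd)
  if (nsd > 0) y <- y + noise

  truth <- data.frame(sample_id = sampleId, compound = compounds$name,
    rt = compounds$rt, is_biomarker = compounds$is_biomarker,
    is_anchor = compounds$is_anchor, included = included,
    true_area = ifelse(included, area, NA_real_),
    true_apex = apex_t, apex_height = apex_h,
    rt_shift = shift, stringsAsFactors = FALSE)

  list(chromatogram = Chromatogram(sampleId, t, y, stage = "raw"),
       truth = truth)
}

# Canonical train/test role assignment: the first floor(nCRC/2) CRC
# samples (manifest order) and the same number of HC samples train;
# everything else tests. "random" draws the training ids instead.
.assignRoles <- function(manifest, mode = c("canonical", "random")) {
  mode <- match.arg(mode)
  crc <- which(manifest$group == "CRC")
  hc <- which(manifest$group == "HC")
  nTrain <- floor(length(crc) / 2)
  trainIdx <- if (mode == "canonical") {
    c(crc[seq_len(min(nTrain, length(crc)))], hc[seq_len(min(nTrain, length(hc)))])
  } else {
    c(sample(crc, min(nTrain, length(crc))), sample(hc, min(nTrain, length(hc))))
  }
  manifest$role <- "test"
  manifest$role[trainIdx] <- "train"
  manifest
}

#' Simulate a breath cohort
#'
#' Generates `nCRC + nHC` chromatograms from one cohort-level compound
#' table (library compounds plus shared unannotated extras), a sample
#' manifest with group labels and a train/test split, and the complete
#' ground truth (per-compound true areas and apexes, the planted
#' biomarker panel, and the ids of any deliberately corrupted samples).
#' Fully reproducible from `config@seed`. With the default 36 CRC / 32 HC
#' cohort the canonical split is 18+18 training and 18+14 testing.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `chromatograms` (named list of [Chromatogram-class]),
#'   `manifest` (data.frame sample_id, group, role), `truth` (list with
#'   `peaks`, `panel`, `qc`, `compounds`).
#' @export
simulateCohort <- function(config) {
  stopifnot(validObject(config))
  set.seed(config@seed)
  compounds <- .compoundTable(config)
  ids <- c(sprintf("CRC%02d", seq_len(config@nCRC)),
           sprintf("HC%02d", seq_len(config@nHC)))
  groups <- rep(c("CRC", "HC"), c(config@nCRC, config@nHC))
  chroms <- vector("list", length(ids))
  names(chroms) <- ids
  truthPeaks <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sim <- simulateChromatogram(config, groups[i], ids[i], compounds)
    chroms[[i]] <- sim$chromatogram
    truthPeaks[[i]] <- sim$truth
  }
  manifest <- data.frame(sample_id = ids, group = groups,
                         role = NA_character_, stringsAsFactors = FALSE)
  manifest <- .assignRoles(manifest, config@splitMode)

  corrupted <- character(0)
  if (config@inadequateFraction > 0) {
    inj <- injectInadequate(chroms, config@inadequateFraction,
                            anchorRTs = config@anchorRTs,
                            saturationLevel = config@saturationLevel)
    chroms <- inj$samples
    corrupted <- inj$corrupted
  }

  panel <- compounds[compounds$is_biomarker,
                     c("rt", "name", "is_library"), drop = FALSE]
  list(chromatograms = chroms, manifest = manifest,
       truth = list(peaks = do.call(rbind, truthPeaks), panel = panel,
                    qc = corrupted, compounds = compounds))
}

#' Corrupt a fraction of samples to be technically inadequate
#'
#' Selects `floor(fraction * n)` samples without replacement and corrupts
#' each by one of three modes chosen at random: (a) global intensity
#' scaled far below the cohort total-signal QC floor, (b) detector
#' saturation (the trace rescaled so that >5\% of points clip at the
#' detector full scale), or (c) removal of all anchor peaks (each anchor
#' window replaced by linear interpolation). Uses the current RNG stream.
#'
#' @param samples named list of [Chromatogram-class].
#' @param fraction fraction in \[0, 1) of samples to corrupt.
#' @param anchorRTs anchor retention times (needed for mode c).
#' @param saturationLevel detector full-scale value (mode b clips here).
#' @param anchorHalfWidth half width (s) of the excised anchor windows.
#' @return list with `samples` (modified list), `corrupted` (ids),
#'   `modes` (named character: `low_signal`, `saturated`, `missing_anchors`).
#' @export
injectInadequate <- function(samples, fraction, anchorRTs = c(42, 53, 65, 137, 276, 502),
                             saturationLevel = 10, anchorHalfWidth = 12) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  n <- length(samples)
  m <- floor(fraction * n)
  if (m == 0) return(list(samples = samples, corrupted = character(0),
                          modes = character(0)))
  idx <- sample.int(n, m)
  modeNames <- c("low_signal", "saturated", "missing_anchors")
  modes <- modeNames[sample.int(3, m, replace = TRUE)]
  totals <- vapply(samples, function(ch)
    pracma::trapz(rtime(ch), pmax(intensity(ch), 0)), numeric(1))
  medTot <- stats::median(totals)

  for (j in seq_len(m)) {
    ch <- samples[[idx[j]]]
    y <- intensity(ch)
    t <- rtime(ch)
    if (modes[j] == "low_signal") {
      # push the integrated signal to 0.5% of the cohort median, well
      # below the default 1% QC floor
      y <- y * (0.005 * medTot / max(totals[idx[j]], .Machine$double.eps))
    } else if (modes[j] == "saturated") {
      q92 <- stats::quantile(y, 0.92, names = FALSE)
      if (q92 <= 0) q92 <- max(y) / 2
      y <- pmin(y * (saturationLevel / q92) * 1.001, saturationLevel)
    } else {
      for (a in anchorRTs) {
        w <- which(t >= a - anchorHalfWidth & t <= a + anchorHalfWidth)
        if (length(w) > 2) {
          y[w] <- seq(y[w[1]], y[w[length(w)]], length.out = length(w))
        }
      }
    }
    samples[[idx[j]]] <- Chromatogram(sampleId(ch), t, y, processingStage(ch))
  }
  ids <- names(samples)[idx]
  if (is.null(ids)) ids <- as.character(idx)
  names(modes) <- ids
  list(samples = samples, corrupted = ids, modes = modes)
}
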