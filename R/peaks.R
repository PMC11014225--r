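#' @include AllClasses.R
NULL

#' Detect peaks in a baseline-corrected chromatogram
#'
#' Finds local maxima with topographic prominence at least
#' `minProminence` and apex height at least `minSNR` times the robust
#' noise estimate (median absolute deviation of the first differences).
#' Integration bounds are local: on each side of an apex the bound is the
#' valley (minimum) between it and the adjacent detected peak (or the
#' trace edge), moved inward to the last point at which the trace is
#' below `boundFrac` of the apex height. This keeps a large peak's
#' integral from swallowing its smaller neighbours while losing only a
#' negligible sliver of tail.
#'
#' @param chrom a baseline-corrected [Chromatogram-class].
#' @param minProminence minimum prominence in detector units; `NULL`
#'   (default) uses 5 times the noise estimate.
#' @param minSNR minimum apex height in noise units (default 3).
#' @param boundFrac bound-clipping height fraction (default 0.01).
#' @return data.frame of peaks sorted by apex time: `apex_time`,
#'   `apex_height`, `area`, `left`, `right` (bound times, s),
#'   `prominence`.
#' @export
detectPeaks <- function(chrom, minProminence = NULL, minSNR = 3,
                        boundFrac = 0.01) {
  if (processingStage(chrom) != "baseline_corrected")
    stop("detectPeaks requires a baseline-corrected chromatogram")
  y <- intensity(chrom)
  t <- rtime(chrom)
  n <- length(y)
  noise <- .noiseEstimate(y)
  if (is.null(minProminence)) minProminence <- 5 * noise
  pk <- .find_peaks_cpp(y, min_prominence = minProminence,
                        min_height = minSNR * noise)
  if (nrow(pk) == 0L)
    return(data.frame(apex_time = numeric(0), apex_height = numeric(0),
                      area = numeric(0), left = numeric(0), right = numeric(0),
                      prominence = numeric(0)))
  m <- nrow(pk)
  idx <- pk$index
  lb <- integer(m)
  rb <- integer(m)
  for (i in seq_len(m)) {
    a <- idx[i]
    thr <- boundFrac * y[a]
    lo <- if (i > 1) idx[i - 1] else 1L
    seg <- lo:a
    v <- seg[which.min(y[seg])]
    below <- seg[seg >= v & seg < a & y[seg] <= thr]
    lb[i] <- if (length(below)) max(below) else v
    hi <- if (i < m) idx[i + 1] else n
    seg <- a:hi
    v <- seg[which.min(y[seg])]
    below <- seg[seg <= v & seg > a & y[seg] <= thr]
    rb[i] <- if (length(below)) min(below) else v
  }
  area <- vapply(seq_len(m), function(i) .trapzRange(t, y, lb[i], rb[i]),
                 numeric(1))
  data.frame(apex_time = t[idx], apex_height = y[idx],
             area = pmax(area, 0), left = t[lb], right = t[rb],
             prominence = pk$prominence)
}

.trapzRange <- function(t, y, i1, i2) {
  if (i2 <= i1) return(0)
  pracma::trapz(t[i1:i2], y[i1:i2])
}

#' Integrate a peak between its bounds
#'
#' Trapezoidal integral of the corrected trace between the peak bounds.
#' A negative integral (possible after baseline subtraction of a noisy
#' region) is floored at 0 with a warning.
#'
#' @param chrom a [Chromatogram-class].
#' @param left,right integration bounds in seconds, inside the time grid.
#' @return peak area in detector units times seconds.
#' @export
integratePeak <- function(chrom, left, right) {
  t <- rtime(chrom)
  if (left < t[1] || right > t[length(t)] || left >= right)
    stop("integration bounds outside the time grid")
  i1 <- which.min(abs(t - left))
  i2 <- which.min(abs(t - right))
  a <- .trapzRange(t, intensity(chrom), i1, i2)
  if (a < 0) {
    warning("negative integral floored at 0")
    a <- 0
  }
  a
}

#' Align detected peaks across samples
#'
#' Builds the cohort consensus feature grid. A per-sample global
#' retention-time shift is estimated as the median offset of the sample's
#' apexes nearest to each anchor compound; shifted apexes from all
#' samples are then pooled and single-linkage clustered, splitting
#' wherever the gap between consecutive apexes exceeds `splitGap`
#' (half the assignment tolerance by default: pooled apexes of one
#' compound lie dense, so a smaller split gap resolves neighbouring
#' compounds a few seconds apart without shattering real clusters).
#' Clusters present in at least `minPresence` of samples become features;
#' each sample's assignment to a feature is its nearest apex within
#' `tolerance` of the consensus retention time, else absent.
#'
#' @param peaklists named list of per-sample peak data.frames from
#'   [detectPeaks()].
#' @param tolerance assignment tolerance in seconds (default 3).
#' @param splitGap cluster-splitting gap in seconds (default
#'   `tolerance / 2`).
#' @param minPresence minimum fraction of samples a cluster must appear
#'   in (default 0.5).
#' @param anchorRTs anchor retention times for shift estimation; `NULL`
#'   skips shift correction.
#' @param anchorWindow search window around each anchor (default 6 s).
#' @return list: `features` (data.frame `rt`, `presence`), `areas`
#'   (samples x features matrix of peak areas, `NA` = absent),
#'   `apexes` (same shape, matched apex times), `shifts` (named numeric).
#' @export
alignSamples <- function(peaklists, tolerance = 3, minPresence = 0.5,
                         anchorRTs = NULL, anchorWindow = 6,
                         splitGap = tolerance / 2) {
  stopifnot(tolerance > 0, splitGap > 0, minPresence > 0, minPresence <= 1)
  ns <- length(peaklists)
  ids <- names(peaklists)
  if (is.null(ids)) ids <- as.character(seq_len(ns))

  shifts <- stats::setNames(numeric(ns), ids)
  if (!is.null(anchorRTs)) {
    for (s in seq_len(ns)) {
      ap <- peaklists[[s]]$apex_time
      offs <- numeric(0)
      for (a in anchorRTs) {
        if (!length(ap)) next
        d <- ap - a
        j <- which.min(abs(d))
        if (abs(d[j]) <= anchorWindow) offs <- c(offs, d[j])
      }
      if (length(offs)) {
        shifts[s] <- stats::median(offs)
      } else {
        warning(sprintf("no anchors matched in sample %s; assuming zero shift", ids[s]))
      }
    }
  }

  pooled <- do.call(rbind, lapply(seq_len(ns), function(s) {
    pl <- peaklists[[s]]
    if (!nrow(pl)) return(NULL)
    data.frame(sample = s, peak = seq_len(nrow(pl)),
               rt = pl$apex_time - shifts[s], area = pl$area,
               apex = pl$apex_time)
  }))
  if (is.null(pooled) || !nrow(pooled)) {
    return(list(features = data.frame(rt = numeric(0), presence = numeric(0)),
                areas = matrix(NA_real_, ns, 0, dimnames = list(ids, NULL)),
                apexes = matrix(NA_real_, ns, 0, dimnames = list(ids, NULL)),
                shifts = shifts))
  }
  pooled <- pooled[order(pooled$rt), , drop = FALSE]
  cl <- cumsum(c(1, diff(pooled$rt) > splitGap))
  consRT <- tapply(pooled$rt, cl, stats::median)
  presence <- tapply(pooled$sample, cl, function(x) length(unique(x)))
  keep <- which(presence >= minPresence * ns)
  consRT <- as.numeric(consRT[keep])
  presence <- as.numeric(presence[keep])
  ord <- order(consRT)
  consRT <- consRT[ord]
  presence <- presence[ord]

  nf <- length(consRT)
  areas <- matrix(NA_real_, ns, nf, dimnames = list(ids, sprintf("F%03d", seq_len(nf))))
  apexes <- areas
  for (s in seq_len(ns)) {
    p <- pooled[pooled$sample == s, , drop = FALSE]
    if (!nrow(p)) next
    for (f in seq_len(nf)) {
      d <- abs(p$rt - consRT[f])
      j <- which.min(d)
      if (d[j] <= tolerance) {
        areas[s, f] <- p$area[j]
        apexes[s, f] <- p$apex[j]
      }
    }
  }
  list(features = data.frame(rt = consRT, presence = presence),
       areas = areas, apexes = apexes, shifts = shifts)
}

#' Annotate consensus features against a compound library
#'
#' Each feature is annotated with the library compound of nearest
#' retention time within the library tolerance. The match is one-to-one:
#' a library row annotates at most one feature (the closest wins; exact
#' distance ties go to the smaller retention time). Compound names listed
#' at several library retention times are disambiguated with an
#' `@<rt>s` qualifier.
#'
#' @param rts numeric vector of consensus feature retention times.
#' @param library a [CompoundLibrary-class].
#' @return character vector of annotations, `NA` where unannotated.
#' @export
matchLibrary <- function(rts, library) {
  stopifnot(is(library, "CompoundLibrary"))
  rec <- libraryRecords(library)
  tol <- rtTolerance(library)
  dup <- rec$name %in% rec$name[duplicated(rec$name)]
  labels <- ifelse(dup, sprintf("%s @%gs", rec$name, rec$rt_s), rec$name)
  ann <- rep(NA_character_, length(rts))
  if (!length(rts) || !nrow(rec)) return(ann)
  pairs <- expand.grid(f = seq_along(rts), l = seq_len(nrow(rec)))
  pairs$d <- abs(rts[pairs$f] - rec$rt_s[pairs$l])
  pairs <- pairs[pairs$d <= tol, , drop = FALSE]
  pairs <- pairs[order(pairs$d, rec$rt_s[pairs$l]), , drop = FALSE]
  usedF <- logical(length(rts))
  usedL <- logical(nrow(rec))
  for (r in seq_len(nrow(pairs))) {
    f <- pairs$f[r]; l <- pairs$l[r]
    if (usedF[f] || usedL[l]) next
    ann[f] <- labels[l]
    usedF[f] <- TRUE
    usedL[l] <- TRUE
  }
  ann
}

#' Build the samples-by-features abundance table
#'
#' Transforms aligned peak areas into the matrix the biomarker search
#' runs on: `value = log10(area + eps)` with `eps` equal to 1\% of the
#' smallest positive area among the training rows; absent peaks are
#' imputed at the `log10(eps)` floor ("absent = low"); every feature is
#' then centered and scaled using parameters fitted on the training rows
#' only and applied to all rows, so no information from the test rows
#' leaks into the representation. Features with zero variance on the
#' training rows are dropped with a warning.
#'
#' @param alignment result of [alignSamples()], or a samples-by-features
#'   area matrix with `NA` for absent peaks.
#' @param manifest data.frame with `sample_id`, `group`, `role` covering
#'   every row of the area matrix.
#' @param library optional [CompoundLibrary-class] used to annotate the
#'   features.
#' @return a [BreathFeatureSet-class].
#' @export
buildFeatureMatrix <- function(alignment, manifest, library = NULL) {
  areas <- if (is.matrix(alignment)) alignment else alignment$areas
  rts <- if (is.matrix(alignment)) {
    a <- attr(alignment, "rt")
    if (is.null(a)) seq_len(ncol(areas)) else a
  } else alignment$features$rt
  ids <- rownames(areas)
  if (is.null(ids)) stop("area matrix must have sample ids as rownames")
  if (is.null(colnames(areas)))
    colnames(areas) <- sprintf("F%03d", seq_len(ncol(areas)))
  mi <- match(ids, manifest$sample_id)
  if (anyNA(mi)) stop("manifest does not cover all samples")
  manifest <- manifest[mi, , drop = FALSE]
  trainRows <- which(manifest$role == "train")
  if (!length(trainRows)) stop("no training rows in manifest")

  trainAreas <- areas[trainRows, , drop = FALSE]
  posAreas <- trainAreas[!is.na(trainAreas) & trainAreas > 0]
  if (!length(posAreas)) stop("no positive training areas")
  eps <- 0.01 * min(posAreas)
  V <- log10(ifelse(is.na(areas), eps, areas + eps))

  ctr <- colMeans(V[trainRows, , drop = FALSE])
  scl <- apply(V[trainRows, , drop = FALSE], 2, stats::sd)
  keep <- which(scl > 0)
  if (length(keep) < ncol(V))
    warning(sprintf("dropping %d feature(s) with zero training variance",
                    ncol(V) - length(keep)))
  V <- sweep(sweep(V[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  rts <- rts[keep]

  ann <- if (!is.null(library)) matchLibrary(rts, library) else rep(NA_character_, length(rts))
  rd <- S4Vectors::DataFrame(rt = rts, annotation = ann)
  rownames(rd) <- colnames(V)
  cd <- S4Vectors::DataFrame(group = manifest$group, role = manifest$role)
  rownames(cd) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = t(V)), rowData = rd, colData = cd,
    metadata = list(transform = list(epsilon = eps, center = ctr[keep],
                                     scale = scl[keep],
                                     train_ids = ids[trainRows])))
  new("BreathFeatureSet", se)
}
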