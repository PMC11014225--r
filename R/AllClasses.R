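#' @include AllGenerics.R
#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom Rcpp sourceCpp
#' @useDynLib breathpanel, .registration = TRUE
NULL

.CHROM_STAGES <- c("raw", "denoised", "baseline_corrected")

#' Chromatogram of one breath sample
#'
#' A single gas-chromatography detector trace: a uniform time grid in
#' seconds and the detector intensity at each grid point, together with a
#' sample identifier and a processing-stage marker (`raw`, `denoised` or
#' `baseline_corrected`).
#'
#' @slot sampleId character(1) sample identifier.
#' @slot times numeric, strictly increasing uniform grid in seconds.
#' @slot intensities numeric, detector units, same length as `times`.
#' @slot stage character(1), one of `raw`, `denoised`, `baseline_corrected`.
#' @export
setClass("Chromatogram",
  representation(sampleId = "character", times = "numeric",
                 intensities = "numeric", stage = "character"),
  prototype(stage = "raw"))

setValidity("Chromatogram", function(object) {
  t <- object@times
  y <- object@intensities
  if (length(object@sampleId) != 1L) return("sampleId must be a single string")
  if (length(t) != length(y)) return("times and intensities differ in length")
  if (length(t) < 16L) return("trace must have at least 16 samples")
  dt <- diff(t)
  if (any(dt <= 0)) return("times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9 * max(abs(dt)))
    return("time grid must be uniform (within 1e-9 relative tolerance)")
  if (anyNA(y)) return("intensities contain NA")
  if (!(object@stage %in% .CHROM_STAGES))
    return(sprintf("stage must be one of %s", paste(.CHROM_STAGES, collapse = ", ")))
  TRUE
})

#' Construct a Chromatogram
#'
#' @param sampleId sample identifier.
#' @param times uniform, strictly increasing time grid (seconds).
#' @param intensities detector intensities, same length as `times`.
#' @param stage processing stage (default `"raw"`).
#' @return A [Chromatogram-class] object.
#' @export
Chromatogram <- function(sampleId, times, intensities, stage = "raw") {
  new("Chromatogram", sampleId = as.character(sampleId), times = as.numeric(times),
      intensities = as.numeric(intensities), stage = stage)
}

#' @describeIn Chromatogram sample identifier
#' @param object a `Chromatogram`
#' @export
setMethod("sampleId", "Chromatogram", function(object) object@sampleId)

#' @describeIn Chromatogram time grid (seconds)
#' @export
setMethod("rtime", "Chromatogram", function(object) object@times)

#' @describeIn Chromatogram detector intensities
#' @export
setMethod("intensity", "Chromatogram", function(object) object@intensities)

#' @describeIn Chromatogram processing stage
#' @export
setMethod("processingStage", "Chromatogram", function(object) object@stage)

setMethod("show", "Chromatogram", function(object) {
  t <- object@times
  cat(sprintf("Chromatogram '%s' [%s]\n", object@sampleId, object@stage))
  cat(sprintf("  %d points, %.1f-%.1f s (%.3g Hz), intensity range [%.4g, %.4g]\n",
              length(t), t[1], t[length(t)], 1 / (t[2] - t[1]),
              min(object@intensities), max(object@intensities)))
})

#' Retention-time compound library
#'
#' Records of (retention time in seconds, compound name) used to annotate
#' detected peaks, with a retention-time match tolerance. Records are kept
#' sorted by retention time; duplicated names (the same compound eluting at
#' two library positions) are allowed and later annotated with an `@<rt>s`
#' qualifier to stay unambiguous.
#'
#' @slot records data.frame with columns `rt_s` and `name`, sorted by `rt_s`.
#' @slot tolerance numeric(1), match tolerance in seconds.
#' @export
setClass("CompoundLibrary",
  representation(records = "data.frame", tolerance = "numeric"),
  prototype(tolerance = 3))

setValidity("CompoundLibrary", function(object) {
  r <- object@records
  if (!all(c("rt_s", "name") %in% names(r))) return("records need rt_s and name columns")
  if (nrow(r) && any(r$rt_s <= 0)) return("retention times must be positive")
  if (is.unsorted(r$rt_s)) return("records must be sorted by retention time")
  if (length(object@tolerance) != 1L || object@tolerance <= 0)
    return("tolerance must be a single positive number")
  TRUE
})

#' @describeIn CompoundLibrary the (rt_s, name) record table
#' @param object a `CompoundLibrary`
#' @export
setMethod("libraryRecords", "CompoundLibrary", function(object) object@records)

#' @describeIn CompoundLibrary retention-time match tolerance (seconds)
#' @export
setMethod("rtTolerance", "CompoundLibrary", function(object) object@tolerance)

setMethod("show", "CompoundLibrary", function(object) {
  r <- object@records
  cat(sprintf("CompoundLibrary: %d records, RT %s-%s s, tolerance %.3g s\n",
              nrow(r), min(r$rt_s), max(r$rt_s), object@tolerance))
  dup <- unique(r$name[duplicated(r$name)])
  if (length(dup))
    cat(sprintf("  %d name(s) listed at multiple retention times\n", length(dup)))
})

#' Two-class Fisher linear discriminant model
#'
#' A linear discriminant for two classes: a weight vector `w`, a decision
#' threshold, and the class labels (positive class first). The score of a
#' sample `x` is `w . x`; the positive class is predicted when the score is
#' greater than or equal to the threshold (scores exactly at the boundary
#' are called positive).
#'
#' @slot weights numeric weight vector, one entry per feature.
#' @slot threshold numeric(1) decision threshold on the score.
#' @slot classes character(2): positive class, negative class.
#' @slot shrinkage numeric(1) in \[0, 1\]: covariance shrinkage used in the fit.
#' @slot means numeric matrix 2 x p of training class means (rows: positive,
#'   negative).
#' @export
setClass("LDAModel",
  representation(weights = "numeric", threshold = "numeric",
                 classes = "character", shrinkage = "numeric", means = "matrix"))

setValidity("LDAModel", function(object) {
  w <- object@weights
  if (!length(w) || anyNA(w) || any(!is.finite(w))) return("weights must be finite")
  if (all(w == 0)) return("weights must be nonzero")
  if (length(object@classes) != 2L) return("exactly two class labels required")
  if (object@shrinkage < 0 || object@shrinkage > 1) return("shrinkage must be in [0, 1]")
  TRUE
})

setMethod("show", "LDAModel", function(object) {
  cat(sprintf("LDAModel (%s vs %s): %d feature(s), shrinkage %.3g, threshold %.4g\n",
              object@classes[1], object@classes[2], length(object@weights),
              object@shrinkage, object@threshold))
})

#' Confusion-matrix counts and diagnostic percentages
#'
#' Counts of true/false positives/negatives, with the derived diagnostic
#' proportions (sensitivity, specificity, positive and negative predictive
#' value, accuracy) as percentages rounded half-away-from-zero to one
#' decimal. Ratios with a zero denominator are `NA`, never 0.
#'
#' @slot tp,fp,tn,fn integer counts.
#' @slot sensitivity,specificity,ppv,npv,accuracy numeric percentages
#'   (1 decimal; `NA` when undefined).
#' @export
setClass("ConfusionMetrics",
  representation(tp = "integer", fp = "integer", tn = "integer", fn = "integer",
                 sensitivity = "numeric", specificity = "numeric",
                 ppv = "numeric", npv = "numeric", accuracy = "numeric"))

setMethod("show", "ConfusionMetrics", function(object) {
  cat(sprintf("ConfusionMetrics: tp=%d fp=%d tn=%d fn=%d\n",
              object@tp, object@fp, object@tn, object@fn))
  cat(sprintf("  sens %.1f%%  spec %.1f%%  ppv %.1f%%  npv %.1f%%  acc %.1f%%\n",
              object@sensitivity, object@specificity, object@ppv, object@npv,
              object@accuracy))
})

#' Feature-subset search result
#'
#' Ranking of evaluated feature subsets by leave-one-out cross-validated
#' accuracy, with the training-set Fisher separation deciding among
#' subsets whose accuracies are within one cross-validation fold of the
#' top (a one-fold difference on a few dozen samples carries no
#' evidence). The best subset is the first row of the ranking.
#'
#' @slot ranking data.frame: one row per evaluated subset with the subset
#'   member indices, `accuracy` and `separation`; the top accuracy band
#'   is sorted by separation, the remainder by (accuracy, separation).
#' @slot best integer vector of feature indices of the winning subset.
#' @slot mode character(1): `exhaustive` or `greedy`.
#' @slot nEvaluated numeric(1): number of subsets scored.
#' @slot k integer(1): subset size.
#' @export
setClass("SubsetSearchResult",
  representation(ranking = "data.frame", best = "integer", mode = "character",
                 nEvaluated = "numeric", k = "integer"))

setValidity("SubsetSearchResult", function(object) {
  r <- object@ranking
  if (!all(c("subset", "accuracy", "separation") %in% names(r)))
    return("ranking needs subset, accuracy, separation columns")
  if (nrow(r) && (any(r$accuracy < 0) || any(r$accuracy > 1)))
    return("accuracy must lie in [0, 1]")
  if (!object@mode %in% c("exhaustive", "greedy"))
    return("mode must be exhaustive or greedy")
  TRUE
})

#' @describeIn SubsetSearchResult indices of the winning subset
#' @param object a `SubsetSearchResult`
#' @export
setMethod("bestSubset", "SubsetSearchResult", function(object) object@best)

#' @describeIn SubsetSearchResult full ranking table
#' @export
setMethod("subsetRanking", "SubsetSearchResult", function(object) object@ranking)

setMethod("show", "SubsetSearchResult", function(object) {
  cat(sprintf("SubsetSearchResult: %s search, k=%d, %d subset(s) evaluated\n",
              object@mode, object@k, object@nEvaluated))
  cat(sprintf("  best: {%s}  cv accuracy %.3f\n",
              paste(object@best, collapse = ", "), object@ranking$accuracy[1]))
})

#' Diagnostic evaluation report
#'
#' Confusion metrics of a fitted panel on the training, testing and
#' combined sample sets, per-sample predictions and scores, the panel
#' identity, and principal-component scores of the panel features.
#'
#' @slot training,testing,combined [ConfusionMetrics-class] per set.
#' @slot predictions data.frame: sample_id, group, role, score, predicted.
#' @slot panel character vector of panel feature names.
#' @slot pca list with `scores`, `loadings`, `explained` (or empty).
#' @slot model the fitted [LDAModel-class].
#' @export
setClass("EvaluationReport",
  representation(training = "ConfusionMetrics", testing = "ConfusionMetrics",
                 combined = "ConfusionMetrics", predictions = "data.frame",
                 panel = "character", pca = "list", model = "LDAModel"))

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport for panel {%s}\n", paste(object@panel, collapse = ", ")))
  for (set in c("training", "testing", "combined")) {
    m <- slot(object, set)
    cat(sprintf("  %-9s n=%2d  acc %.1f%%  sens %.1f%%  spec %.1f%%\n", set,
                m@tp + m@fp + m@tn + m@fn, m@accuracy, m@sensitivity, m@specificity))
  }
})

#' Breath VOC feature set
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the aligned
#' samples-by-features abundance table: features in rows (with consensus
#' retention time and optional compound annotation in `rowData`), samples
#' in columns (with group and train/test role in `colData`). The single
#' assay `abundance` contains log10 peak areas centered and scaled per
#' feature with parameters fitted on the training samples only; the full
#' transform descriptor (epsilon floor, centers, scales, training ids) is
#' stored in `metadata(x)$transform`.
#'
#' @export
setClass("BreathFeatureSet", contains = "SummarizedExperiment")

setValidity("BreathFeatureSet", function(object) {
  rd <- rowData(object)
  if (!"rt" %in% names(rd)) return("rowData must contain consensus retention time 'rt'")
  if (nrow(object) > 1 && any(diff(rd$rt) <= 0))
    return("consensus retention times must be strictly increasing")
  if (!all(c("group", "role") %in% names(colData(object))))
    return("colData must contain 'group' and 'role'")
  if (is.null(metadata(object)$transform)) return("missing transform descriptor")
  if (anyNA(assay(object))) return("abundance matrix must have no missing entries")
  TRUE
})

#' @describeIn BreathFeatureSet consensus feature retention times (seconds)
#' @param object a `BreathFeatureSet`
#' @export
setMethod("featureRT", "BreathFeatureSet", function(object) rowData(object)$rt)

#' @describeIn BreathFeatureSet compound annotations (NA when unannotated)
#' @export
setMethod("featureAnnotation", "BreathFeatureSet",
          function(object) rowData(object)$annotation)

#' @describeIn BreathFeatureSet samples-by-features abundance matrix
#' @export
setMethod("featureValues", "BreathFeatureSet", function(object) t(assay(object, "abundance")))

#' @describeIn BreathFeatureSet the fitted transform descriptor
#' @export
setMethod("transformDescriptor", "BreathFeatureSet",
          function(object) metadata(object)$transform)

#' @describeIn BreathFeatureSet ids of the training samples
#' @export
setMethod("trainSamples", "BreathFeatureSet",
          function(object) colnames(object)[colData(object)$role == "train"])
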