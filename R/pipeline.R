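#' @include AllClasses.R simulate.R
NULL

#' Default pipeline configuration
#'
#' A nested list mirroring the pipeline stages. `simulate` holds the
#' arguments of [simulationConfig()]; `preprocess`, `qc`, `peaks`,
#' `discover` and `evaluate` hold the tunables of their stages. All
#' randomness flows from the single global `seed` through fixed
#' per-stage substreams, so reruns are bit-identical and the stages can
#' be executed separately with the same result.
#'
#' @param seed global RNG seed.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(nCRC = 36, nHC = 32, libraryPath = "",
                    effectSize = 1.5, inadequateFraction = 0,
                    nExtraPeaks = 40, samplingRate = 10, duration = 800,
                    splitMode = "canonical"),
    preprocess = list(window = 21, polyorder = 3, smoothness = 1e6,
                      asymmetry = 0.01, maxIter = 10),
    qc = list(ceiling = 10, floorFrac = 0.01, minAnchors = 3,
              maxSaturation = 0.05),
    peaks = list(minSNR = 3, tolerance = 3, minPresence = 0.5),
    discover = list(k = 3, mode = "exhaustive", shrinkage = 0.1),
    evaluate = list(shrinkage = 0.1)
  )
}

#' Read a pipeline configuration file
#'
#' YAML with the sections of [defaultRunConfig()]; missing keys take the
#' defaults, unknown keys are rejected.
#'
#' @param path YAML file.
#' @param seed optional seed override.
#' @return resolved configuration list.
#' @export
readRunConfig <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  extraSim <- setdiff(names(formals(simulationConfig)), "seed")
  for (sec in names(user)) {
    if (!sec %in% names(cfg)) stop("unknown config section: ", sec)
    if (sec == "seed") { cfg$seed <- user$seed; next }
    allowed <- if (sec == "simulate") extraSim else names(cfg[[sec]])
    for (key in names(user[[sec]])) {
      if (!key %in% allowed)
        stop(sprintf("unknown config key: %s.%s", sec, key))
      cfg[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  if (!is.null(seed)) cfg$seed <- seed
  cfg
}

# fixed per-stage seed substreams derived from the global seed
.stageSeed <- function(seed, stage) {
  offs <- c(simulate = 101L, qc = 211L, peaks = 307L, discover = 401L,
            evaluate = 503L)
  (as.integer(seed) + offs[[stage]]) %% .Machine$integer.max
}

#' Run the full breath-analysis pipeline
#'
#' Executes simulate (unless chromatograms are supplied) -> quality
#' control on the raw traces -> de-noising and baseline correction ->
#' peak detection, alignment, annotation and feature-matrix construction
#' -> exhaustive panel search on the training rows only -> evaluation of
#' the winning panel on training, testing and combined sets. When
#' `outDir` is given, every stage's outputs plus the fully resolved
#' configuration are written there; a rerun with the same configuration
#' is bit-identical.
#'
#' @param config configuration list from [defaultRunConfig()] /
#'   [readRunConfig()].
#' @param outDir optional output directory.
#' @param chromatograms optional named list of raw [Chromatogram-class]
#'   (skips simulation; requires `manifest`).
#' @param manifest manifest data.frame when `chromatograms` is given.
#' @param writeChromatograms also write every simulated trace as CSV.
#' @return (invisibly) list: `report` ([EvaluationReport-class]),
#'   `search`, `featureSet`, `qc`, `manifest`, `truth`, `config`.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = NULL,
                        chromatograms = NULL, manifest = NULL,
                        writeChromatograms = FALSE) {
  simCfg <- do.call(simulationConfig,
                    c(config$simulate, list(seed = .stageSeed(config$seed, "simulate"))))
  truth <- NULL
  if (is.null(chromatograms)) {
    message("[simulate] generating ", simCfg@nCRC, " CRC + ", simCfg@nHC, " HC samples")
    cohort <- simulateCohort(simCfg)
    chromatograms <- cohort$chromatograms
    manifest <- cohort$manifest
    truth <- cohort$truth
  } else if (is.null(manifest)) {
    stop("manifest required when chromatograms are supplied")
  }

  anchors <- simCfg@anchorRTs
  qc <- cohortQC(chromatograms, ceiling = config$qc$ceiling,
                 anchorRTs = anchors, floorFrac = config$qc$floorFrac,
                 minAnchors = config$qc$minAnchors,
                 maxSaturation = config$qc$maxSaturation)
  retained <- suppressMessages(filterInadequate(chromatograms, qc))
  message(sprintf("[qc] %d of %d samples adequate (%d excluded)",
                  length(retained), length(chromatograms),
                  length(chromatograms) - length(retained)))
  manifest <- manifest[manifest$sample_id %in% names(retained), , drop = FALSE]
  set.seed(.stageSeed(config$seed, "qc"))  # only consumed by a random split
  manifest <- .assignRoles(manifest, simCfg@splitMode)

  message("[preprocess] de-noising and baseline-correcting ", length(retained), " traces")
  corrected <- lapply(retained, function(ch)
    baselineCorrect(denoise(ch, config$preprocess$window, config$preprocess$polyorder),
                    smoothness = config$preprocess$smoothness,
                    asymmetry = config$preprocess$asymmetry,
                    maxIter = config$preprocess$maxIter))

  peaklists <- lapply(corrected, detectPeaks, minSNR = config$peaks$minSNR)
  alignment <- alignSamples(peaklists, tolerance = config$peaks$tolerance,
                            minPresence = config$peaks$minPresence,
                            anchorRTs = anchors)
  message(sprintf("[peaks] %d consensus features from %d samples",
                  nrow(alignment$features), length(peaklists)))
  lib <- .resolveLibrary(simCfg)
  fs <- buildFeatureMatrix(alignment, manifest, library = lib)

  search <- subsetSearch(fs, k = config$discover$k, mode = config$discover$mode,
                         shrinkage = config$discover$shrinkage)
  message(sprintf("[discover] %s search evaluated %d subsets; best {%s} (cv accuracy %.3f)",
                  search@mode, search@nEvaluated,
                  paste(bestSubset(search), collapse = ","),
                  subsetRanking(search)$accuracy[1]))

  report <- evaluatePanel(fs, bestSubset(search),
                          shrinkage = config$evaluate$shrinkage)
  message(sprintf("[evaluate] combined accuracy %.1f%% (sens %.1f%%, spec %.1f%%)",
                  report@combined@accuracy, report@combined@sensitivity,
                  report@combined@specificity))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(config, file.path(outDir, "config_resolved.yaml"))
    writeManifest(manifest, file.path(outDir, "manifest.csv"))
    writeQCReports(qc, file.path(outDir, "qc_reports.jsonl"))
    V <- featureValues(fs)
    utils::write.csv(cbind(data.frame(sample_id = rownames(V)), as.data.frame(V)),
                     file.path(outDir, "feature_matrix.csv"), row.names = FALSE)
    jsonlite::write_json(
      c(transformDescriptor(fs),
        list(feature_rt = featureRT(fs), annotation = featureAnnotation(fs))),
      file.path(outDir, "feature_transform.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
    utils::write.csv(subsetRanking(search), file.path(outDir, "search_ranking.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(panel = report@panel, indices = bestSubset(search),
           annotation = featureAnnotation(fs)[bestSubset(search)],
           rt = featureRT(fs)[bestSubset(search)],
           cv_accuracy = subsetRanking(search)$accuracy[1]),
      file.path(outDir, "best_panel.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
    writeEvaluationReport(report, file.path(outDir, "evaluation.json"))
    writeMetricsTable(report, file.path(outDir, "metrics_table.csv"))
    if (writeChromatograms) {
      cdir <- file.path(outDir, "chromatograms")
      dir.create(cdir, showWarnings = FALSE)
      for (ch in chromatograms)
        writeChromatogram(ch, file.path(cdir, paste0(sampleId(ch), ".csv")))
    }
  }

  invisible(list(report = report, search = search, featureSet = fs, qc = qc,
                 manifest = manifest, truth = truth, config = config))
}
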