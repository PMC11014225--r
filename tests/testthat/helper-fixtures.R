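# fixtures are built in code: a miniature compound library and compact
# simulation configs keep the unit tests fast

miniLibraryPath <- function(rts = c(42, 60, 90), names = sprintf("compound_%d", seq_along(rts))) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("rt_s\tname", sprintf("%g\t%s", rts, names)), path)
  path
}

# single-compound, noise-free configuration for area oracles
cleanSingleCfg <- function(rt = 50, duration = 100, ...) {
  simulationConfig(nCRC = 2, nHC = 2, libraryPath = miniLibraryPath(rt, "only"),
                   biomarkerRTs = rt, anchorRTs = numeric(0),
                   baselineAmplitude = 0, noiseSD = 0, nExtraPeaks = 0,
                   duration = duration, rtGlobalJitterSD = 0,
                   rtPeakJitterSD = 0, ...)
}

# small multi-compound config (anchors at 42/60, biomarker at 90)
smallCfg <- function(nCRC = 6, nHC = 6, ...) {
  simulationConfig(nCRC = nCRC, nHC = nHC,
                   libraryPath = miniLibraryPath(c(42, 60, 90, 120, 150)),
                   biomarkerRTs = 90, anchorRTs = c(42, 60),
                   nExtraPeaks = 0, duration = 200, ...)
}

# a baseline-corrected chromatogram built directly from a function of time
directChrom <- function(y, dt = 0.1, stage = "baseline_corrected", id = "X1") {
  Chromatogram(id, seq(0, by = dt, length.out = length(y)), y, stage = stage)
}

# samples x features area matrix -> BreathFeatureSet via the standard
# constructor, with the first half of each group training
featureSetFromAreas <- function(areas, groups) {
  ids <- sprintf("%s%02d", groups, stats::ave(seq_along(groups), groups, FUN = seq_along))
  rownames(areas) <- ids
  manifest <- data.frame(sample_id = ids, group = groups, role = "test",
                         stringsAsFactors = FALSE)
  manifest <- breathpanel:::.assignRoles(manifest, "canonical")
  attr(areas, "rt") <- seq_len(ncol(areas)) * 10
  buildFeatureMatrix(areas, manifest)
}
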