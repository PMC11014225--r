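#' @include AllClasses.R
NULL

#' Read a chromatogram CSV
#'
#' Expects the plain-text dialect used throughout the package: one header
#' line `time_s,intensity`, then one `time,intensity` pair per line.
#' Parse problems (ragged rows, non-numeric cells, non-increasing or
#' non-uniform times, traces shorter than 16 points) raise an error that
#' names the offending line.
#'
#' @param path file path; the sample id defaults to the file name without
#'   extension.
#' @param sampleId overrides the sample id.
#' @return a [Chromatogram-class] with stage `raw`.
#' @export
readChromatogram <- function(path, sampleId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop(path, ": header-only or empty file")
  fields <- strsplit(lines[-1], ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2))
    stop(path, ": line ", which(nf != 2)[1] + 1L, ": expected 2 comma-separated fields")
  tvals <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 1)))
  yvals <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  bad <- which(is.na(tvals) | is.na(yvals))
  if (length(bad)) stop(path, ": line ", bad[1] + 1L, ": non-numeric value")
  if (length(tvals) < 16) stop(path, ": trace too short (", length(tvals), " rows; need >= 16)")
  nonmono <- which(diff(tvals) <= 0)
  if (length(nonmono)) stop(path, ": line ", nonmono[1] + 2L, ": times not strictly increasing")
  if (is.null(sampleId)) sampleId <- sub("\\.[^.]*$", "", basename(path))
  Chromatogram(sampleId, tvals, yvals, stage = "raw")
}

#' Write a chromatogram CSV
#'
#' @param chrom a [Chromatogram-class].
#' @param path output path (`<sample_id>.csv` by convention).
#' @export
writeChromatogram <- function(chrom, path) {
  data.table::fwrite(data.table::data.table(time_s = rtime(chrom),
                                            intensity = intensity(chrom)),
                     path)
  invisible(path)
}

#' Read or write a sample manifest
#'
#' Comma-separated `sample_id,group,role` with `group` in CRC/HC and
#' `role` in train/test.
#'
#' @param path file path.
#' @return data.frame with the three columns.
#' @export
readManifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "role")
  if (!all(need %in% names(m))) stop("manifest needs columns ", paste(need, collapse = ", "))
  if (!all(m$group %in% c("CRC", "HC"))) stop("group must be CRC or HC")
  if (!all(m$role %in% c("train", "test"))) stop("role must be train or test")
  m[need]
}

#' @rdname readManifest
#' @param manifest data.frame with `sample_id`, `group`, `role`.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compound libraries
#'
#' `readCompoundLibrary` reads a tab-separated table `rt_s<TAB>name` (one
#' header line) and returns the records sorted by retention time;
#' `defaultCompoundLibrary` returns the library of compounds identified
#' in human breath by portable GC-MS that ships with the package (61
#' records, 9-768 s).
#'
#' @param path TSV path.
#' @param tolerance retention-time match tolerance in seconds (default 3).
#' @return a [CompoundLibrary-class].
#' @export
readCompoundLibrary <- function(path, tolerance = 3) {
  r <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("rt_s", "name") %in% names(r)))
    stop("library needs columns rt_s and name")
  r <- r[order(r$rt_s), c("rt_s", "name")]
  rownames(r) <- NULL
  new("CompoundLibrary", records = r, tolerance = tolerance)
}

#' @rdname readCompoundLibrary
#' @export
defaultCompoundLibrary <- function(tolerance = 3) {
  readCompoundLibrary(system.file("extdata", "breath_compound_library.tsv",
                                  package = "breathpanel", mustWork = TRUE),
                      tolerance = tolerance)
}

#' Serialise an evaluation report
#'
#' `evaluationReportAsList` converts an [EvaluationReport-class] into
#' plain lists (for JSON); `writeEvaluationReport` writes it as JSON and
#' `writeMetricsTable` writes the one-decimal metrics table CSV.
#'
#' @param report an [EvaluationReport-class].
#' @return a nested list mirroring the report.
#' @export
evaluationReportAsList <- function(report) {
  met <- function(m) list(tp = m@tp, fp = m@fp, tn = m@tn, fn = m@fn,
                          sensitivity = m@sensitivity, specificity = m@specificity,
                          ppv = m@ppv, npv = m@npv, accuracy = m@accuracy)
  list(panel = report@panel,
       training = met(report@training), testing = met(report@testing),
       combined = met(report@combined),
       predictions = report@predictions,
       pca = if (length(report@pca))
         list(explained = report@pca$explained,
              loadings = report@pca$loadings,
              scores = cbind(data.frame(sample_id = rownames(report@pca$scores)),
                             as.data.frame(report@pca$scores)))
       else NULL)
}

#' @rdname evaluationReportAsList
#' @param path output path.
#' @export
writeEvaluationReport <- function(report, path) {
  jsonlite::write_json(evaluationReportAsList(report), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' @rdname evaluationReportAsList
#' @export
writeMetricsTable <- function(report, path) {
  tab <- metricsTable(report)
  out <- cbind(data.frame(statistic = rownames(tab)),
               as.data.frame(lapply(tab, function(x) formatC(x, format = "fg"))))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-sample QC reports as JSON lines
#'
#' @param reports QC data.frame from [cohortQC()].
#' @param path output path (one JSON record per line).
#' @export
writeQCReports <- function(reports, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(reports))) {
    rec <- as.list(reports[i, , drop = FALSE])
    rec$reasons <- if (nzchar(rec$reasons)) strsplit(rec$reasons, ";")[[1]] else character(0)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
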