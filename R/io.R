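# atomic write: temp file in the same directory, then rename
.atomicWrite <- function(writeFun, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeFun(tmp)
  if (!file.rename(tmp, path))
    stop("atomic write failed for ", path)
  invisible(path)
}

.checkHeader <- function(df, need, what, path) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("malformed %s header in %s: missing column(s) %s",
                 what, path, paste(miss, collapse = ", ")))
}

.checkNumeric <- function(df, cols, what, path) {
  for (cl in cols) {
    bad <- which(!is.na(df[[cl]]) & is.na(suppressWarnings(
      as.numeric(as.character(df[[cl]])))))
    if (length(bad))
      stop(sprintf("non-numeric value in %s column '%s' of %s (row %d)",
                   what, cl, path, bad[1]))
    df[[cl]] <- as.numeric(as.character(df[[cl]]))
  }
  df
}

#' Read a ratiometric trace with its event log and solutions
#'
#' Trace file: CSV with header `time_s,f440,f495`. Events file: TSV with
#' header `time_s<TAB>solution_id`. Solutions file: YAML (or JSON) mapping
#' solution id to SolutionSpec fields (`naPresent`, `co2Present`,
#' `nh4clMM`, `hco3MM`, `phO`, `highKNigericin`).
#'
#' @param tracePath,eventsPath,solutionsPath file paths.
#' @return a [RatioTrace-class].
#' @export
readTrace <- function(tracePath, eventsPath, solutionsPath) {
  for (p in c(tracePath, eventsPath, solutionsPath))
    if (!file.exists(p)) stop("file not found: ", p)
  tr <- utils::read.csv(tracePath, stringsAsFactors = FALSE)
  .checkHeader(tr, c("time_s", "f440", "f495"), "trace", tracePath)
  tr <- .checkNumeric(tr, c("time_s", "f440", "f495"), "trace", tracePath)
  ev <- utils::read.delim(eventsPath, stringsAsFactors = FALSE)
  .checkHeader(ev, c("time_s", "solution_id"), "events", eventsPath)
  ev <- .checkNumeric(ev, "time_s", "events", eventsPath)
  raw <- yaml::read_yaml(solutionsPath)
  sols <- lapply(raw, function(s)
    solutionSpec(naPresent = isTRUE(s$naPresent),
                 co2Present = isTRUE(s$co2Present),
                 nh4clMM = s$nh4clMM %||% 0,
                 hco3MM = s$hco3MM %||% if (isTRUE(s$co2Present)) 22 else 0,
                 phO = s$phO %||% 7.4,
                 highKNigericin = isTRUE(s$highKNigericin)))
  ratioTrace(tr$time_s, tr$f440, tr$f495, events = ev, solutions = sols)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trace (with events and solutions) to the standard dialects
#'
#' Inverse of [readTrace()]; writes are atomic (temp file + rename).
#'
#' @param trace a [RatioTrace-class].
#' @param tracePath,eventsPath,solutionsPath output paths.
#' @export
writeTrace <- function(trace, tracePath, eventsPath, solutionsPath) {
  .atomicWrite(function(p) utils::write.csv(
    data.frame(time_s = trace@time, f440 = trace@f440, f495 = trace@f495),
    p, row.names = FALSE, quote = FALSE), tracePath)
  .atomicWrite(function(p) utils::write.table(
    trace@events, p, sep = "\t", row.names = FALSE, quote = FALSE),
    eventsPath)
  sols <- lapply(trace@solutions, function(s) list(
    naPresent = s@naPresent, co2Present = s@co2Present, nh4clMM = s@nh4clMM,
    hco3MM = s@hco3MM, phO = s@phO, highKNigericin = s@highKNigericin))
  .atomicWrite(function(p) yaml::write_yaml(sols, p), solutionsPath)
  invisible(NULL)
}

#' Write / read a per-specimen metrics table
#'
#' TSV, one row per specimen x condition, carrying the PhiMetrics fields
#' and QC flags. `readMetrics(writeMetrics(x))` is the identity.
#'
#' @param metrics list of [PhiMetrics-class] (names = specimen ids) or a
#'   data.frame as produced by `metricsToTable`.
#' @param path output path.
#' @return `readMetrics` returns the data.frame.
#' @export
writeMetrics <- function(metrics, path) {
  df <- if (is.data.frame(metrics)) metrics else metricsToTable(metrics)
  .atomicWrite(function(p) utils::write.table(
    df, p, sep = "\t", row.names = FALSE, quote = FALSE, na = ""), path)
  invisible(df)
}

#' @rdname writeMetrics
#' @export
readMetrics <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  .checkHeader(df, c("specimen", "condition", "steady_state_ph",
                     "beta_intrinsic", "j_at_range", "qc_status"),
               "metrics", path)
  df
}

#' @rdname writeMetrics
#' @export
metricsToTable <- function(metrics) {
  stopifnot(is.list(metrics))
  ids <- names(metrics) %||% sprintf("S%03d", seq_along(metrics))
  do.call(rbind, lapply(seq_along(metrics), function(i) {
    m <- metrics[[i]]
    data.frame(specimen = ids[i], condition = m@condition,
               steady_state_ph = m@steadyStatePH,
               steady_state_sd = m@steadyStateSD,
               baseline_ph = m@baselinePH, nadir_ph = m@nadirPH,
               beta_intrinsic = m@betaIntrinsic,
               beta_source = m@betaSource, j_at_range = m@jAtRange,
               qc_status = m@qcStatus, qc_reason = m@qcReason,
               stringsAsFactors = FALSE)
  }))
}

#' Read and validate a clinical cohort table
#'
#' TSV, one row per patient, empty fields as missing. Categorical columns
#' are checked against their declared level sets; violations are reported
#' with the offending row number. Duplicate patient ids are an error.
#'
#' @param path TSV path.
#' @return validated data.frame with factor columns.
#' @export
readClinicalTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  .checkHeader(df, c("patient_id"), "clinical table", path)
  if (anyDuplicated(df$patient_id))
    stop("duplicated patient_id in ", path, ": row ",
         which(duplicated(df$patient_id))[1])
  levelSets <- list(
    histology = c("ductal", "lobular", "mucinous", "other"),
    grade = c("I", "II", "III", "ungraded"),
    er_group = c("ER_positive", "ER_negative"),
    her2 = c("normal", "overexpressed"),
    ki67_group = c("low", "high"),
    node_status = c("negative", "positive"),
    investigator = NULL)
  for (v in names(levelSets)) {
    if (!v %in% names(df)) next
    lv <- levelSets[[v]]
    if (!is.null(lv)) {
      bad <- which(!is.na(df[[v]]) & !df[[v]] %in% lv)
      if (length(bad))
        stop(sprintf("validation error in %s: undeclared %s level '%s' (row %d)",
                     path, v, df[[v]][bad[1]], bad[1]))
      df[[v]] <- factor(df[[v]], levels = lv)
    } else df[[v]] <- factor(df[[v]])
  }
  numCols <- intersect(c("age", "tumor_size_mm", "nhe1_score", "nbcn1_score",
                         "steady_ph_with_co2", "steady_ph_without_co2",
                         "delta_phi", "j_with_co2", "j_without_co2",
                         "nbc_flux"), names(df))
  .checkNumeric(df, numCols, "clinical table", path)
}

#' Write a clinical cohort table
#'
#' @param patients data.frame.
#' @param path output TSV path.
#' @export
writeClinicalTable <- function(patients, path) {
  .atomicWrite(function(p) utils::write.table(
    patients, p, sep = "\t", row.names = FALSE, quote = FALSE, na = ""),
    path)
  invisible(path)
}

#' Read an expression bundle
#'
#' Expression matrix: TSV with genes/probes as rows (first column `id`),
#' samples as columns. Probe map: TSV `probe<TAB>gene`. Survival: TSV with
#' columns `sample`, `dataset`, `time`, `event`. Sample ids must be
#' unique and consistent across files.
#'
#' @param exprPath,survivalPath,probeMapPath file paths (probe map
#'   optional).
#' @return list with `matrix`, `probeMap` (or NULL), `survival`.
#' @export
readExpressionBundle <- function(exprPath, survivalPath,
                                 probeMapPath = NULL) {
  ex <- utils::read.delim(exprPath, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(ex)[1] != "id")
    stop("malformed expression header in ", exprPath,
         ": first column must be 'id'")
  mat <- as.matrix(ex[, -1, drop = FALSE])
  rownames(mat) <- ex$id
  if (!is.numeric(mat)) stop("non-numeric expression values in ", exprPath)
  surv <- utils::read.delim(survivalPath, stringsAsFactors = FALSE)
  .checkHeader(surv, c("sample", "dataset", "time", "event"), "survival",
               survivalPath)
  surv <- .checkNumeric(surv, c("time", "event"), "survival", survivalPath)
  if (anyDuplicated(surv$sample))
    stop("duplicated sample id in ", survivalPath, ": ",
         surv$sample[duplicated(surv$sample)][1])
  if (!setequal(surv$sample, colnames(mat)))
    stop("sample ids differ between ", exprPath, " and ", survivalPath)
  surv <- surv[match(colnames(mat), surv$sample), ]
  pm <- NULL
  if (!is.null(probeMapPath)) {
    pm <- utils::read.delim(probeMapPath, stringsAsFactors = FALSE)
    .checkHeader(pm, c("probe", "gene"), "probe map", probeMapPath)
  }
  list(matrix = mat, probeMap = pm, survival = surv)
}

#' Write an expression bundle
#'
#' @param mat probes/genes x samples matrix.
#' @param survival data.frame with sample, dataset, time, event.
#' @param exprPath,survivalPath,probeMapPath output paths.
#' @param probeMap optional probe map data.frame.
#' @export
writeExpressionBundle <- function(mat, survival, exprPath, survivalPath,
                                  probeMap = NULL, probeMapPath = NULL) {
  .atomicWrite(function(p) utils::write.table(
    data.frame(id = rownames(mat), mat, check.names = FALSE),
    p, sep = "\t", row.names = FALSE, quote = FALSE), exprPath)
  .atomicWrite(function(p) utils::write.table(
    survival, p, sep = "\t", row.names = FALSE, quote = FALSE),
    survivalPath)
  if (!is.null(probeMap))
    .atomicWrite(function(p) utils::write.table(
      probeMap, p, sep = "\t", row.names = FALSE, quote = FALSE),
      probeMapPath)
  invisible(NULL)
}

#' Write a JSON analysis report atomically
#'
#' @param report named list.
#' @param path output path.
#' @export
writeReport <- function(report, path) {
  .atomicWrite(function(p) jsonlite::write_json(
    report, p, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"),
    path)
  invisible(path)
}
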