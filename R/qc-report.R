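#' Run the consolidated QC battery over a set of runs
#'
#' Computes, for every run, the peptide length distribution, and — when a
#' predictor is supplied — the binder fractions (8-13mers and 9mers only)
#' and the allele-specificity deconvolution composition; with two or more
#' runs, the exclusive replicate-overlap table is added. Every number in
#' the report is reproducible from the echoed configuration (predictor
#' alleles, calibration size and seed) plus the inputs. Any module error
#' propagates, prefixed with the failing stage.
#'
#' @param runs list of [SampleRun-class] objects.
#' @param predictor optional [PssmPredictor-class]; required for binder
#'   fractions and deconvolution (each run then needs a haplotype).
#' @param deconvLengths lengths used for deconvolution (default 9).
#' @return list of class `ipqc_report` with elements `tool`, `config`,
#'   `runs` (per-run metrics) and `overlap`.
#' @export
runQC <- function(runs, predictor = NULL, deconvLengths = 9L) {
  if (!length(runs)) .stopf("[qc/input] no runs supplied")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("[qc/%s] %s", name, conditionMessage(e)))
  }
  config <- list(nRuns = length(runs),
                 deconvLengths = as.integer(deconvLengths))
  if (!is.null(predictor)) {
    config$predictor <- list(
      backend = "pssm",
      alleles = alleles(predictor),
      nBackground = predictor@calibrations[[1L]]@nBackground,
      calibrationSeed = predictor@calibrations[[1L]]@seed)
    missingHap <- vapply(runs, function(r) length(haplotype(r)) == 0L,
                         logical(1))
    if (any(missingHap))
      .stopf("[qc/haplotype] run(s) without haplotype: %s",
             paste(vapply(runs[missingHap], .runLabel, character(1)),
                   collapse = ", "))
  }
  perRun <- lapply(runs, function(run) {
    out <- list(runId = .runLabel(run),
                tissue = tissueLabel(run),
                nPeptides = nPeptides(run),
                lengthDistribution = stage("length_distribution",
                                           lengthDistribution(run)))
    if (!is.null(predictor)) {
      out$binderFraction8to13 <- stage("binder_fraction",
                                       binderFraction(run, predictor, "all_8_13"))
      out$binderFraction9 <- stage("binder_fraction",
                                   binderFraction(run, predictor, "only_9"))
      dec <- stage("deconvolution",
                   deconvoluteSpecificity(run, predictor, deconvLengths))
      out$specificity <- dec[c("composition", "nB", "unassignable")]
    }
    out
  })
  overlap <- if (length(runs) >= 2L)
    stage("overlap", replicateOverlapSets(runs)) else NULL
  structure(list(
    tool = list(name = "ipQC",
                version = as.character(utils::packageVersion("ipQC"))),
    config = config,
    runs = perRun,
    overlap = overlap), class = "ipqc_report")
}

#' Write a QC report to disk
#'
#' Writes `report.json` (the full report; byte-identical across reruns on
#' identical inputs) plus per-run TSV tables (length distribution,
#' specificity composition) and the overlap table.
#'
#' @param report result of [runQC()].
#' @param dir output directory (created if needed).
#' @return the JSON path, invisibly.
#' @export
writeQcReport <- function(report, dir) {
  stopifnot(inherits(report, "ipqc_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonPath <- file.path(dir, "report.json")
  jsonlite::write_json(.reportAsList(report), jsonPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (r in report$runs) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", r$runId)
    utils::write.table(r$lengthDistribution$table,
                       file.path(dir, paste0("lengths_", safe, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(r$specificity))
      utils::write.table(r$specificity$composition,
                         file.path(dir, paste0("specificity_", safe, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$overlap))
    utils::write.table(report$overlap, file.path(dir, "overlap_upset.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(jsonPath)
}

.reportAsList <- function(report) {
  runs <- lapply(report$runs, function(r) {
    out <- list(run_id = r$runId, tissue = r$tissue,
                n_peptides = r$nPeptides,
                length_distribution = list(
                  table = r$lengthDistribution$table,
                  fraction_8_13 = r$lengthDistribution$fraction8to13,
                  fraction_9_of_all = r$lengthDistribution$fraction9OfAll,
                  fraction_9_of_8_13 = r$lengthDistribution$fraction9Of8to13))
    if (!is.null(r$binderFraction8to13)) {
      out$binder_fraction_8_13 <- r$binderFraction8to13
      out$binder_fraction_9 <- r$binderFraction9
      out$specificity <- list(composition = r$specificity$composition,
                              non_binders = r$specificity$nB,
                              unassignable = r$specificity$unassignable)
    }
    out
  })
  list(tool = report$tool, config = report$config, runs = runs,
       overlap = report$overlap)
}

#' Structurally validate a QC report
#'
#' Checks the report against the shipped schema
#' (`system.file("schema", "qc-report.schema.json", package = "ipQC")`):
#' required fields present, counts non-negative, every percentage within
#' \[0, 100\].
#'
#' @param report result of [runQC()].
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validateQcReport <- function(report) {
  if (!inherits(report, "ipqc_report")) .stopf("not an ipqc_report")
  need <- c("tool", "config", "runs")
  miss <- setdiff(need, names(report))
  if (length(miss)) .stopf("report missing field(s): %s",
                           paste(miss, collapse = ", "))
  if (!is.character(report$tool$version)) .stopf("tool.version must be a string")
  pctOk <- function(x) all(is.na(x) | (x >= -1e-9 & x <= 100 + 1e-9))
  for (r in report$runs) {
    ld <- r$lengthDistribution
    if (!pctOk(ld$table$percentage) ||
        !pctOk(c(ld$fraction8to13, ld$fraction9OfAll, ld$fraction9Of8to13)))
      .stopf("percentages out of [0, 100] in run %s", r$runId)
    if (abs(sum(ld$table$percentage) - 100) > 1e-6)
      .stopf("length percentages do not sum to 100 in run %s", r$runId)
    if (!is.null(r$binderFraction8to13) &&
        !pctOk(c(r$binderFraction8to13, r$binderFraction9)))
      .stopf("binder fractions out of [0, 100] in run %s", r$runId)
    if (r$nPeptides < 0) .stopf("negative peptide count in run %s", r$runId)
  }
  if (!is.null(report$overlap) && any(report$overlap$size < 0))
    .stopf("negative overlap sizes")
  invisible(TRUE)
}
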