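#' Protein coverage ratio of a run
#'
#' For every protein with at least one mapped peptide in the run, the
#' coverage ratio is the summed length of its distinct class I peptides
#' divided by the protein length:
#' `ratio(P) = (1 / L(P)) * sum over peptides p of P of L(p)`.
#' Proteolytic contaminants produce nested "ladder" peptide series along
#' one protein and hence extreme ratios, while genuine MHC presentation
#' rarely covers a protein densely. Peptides mapping to k proteins
#' contribute their length to all k; accessions absent from the database
#' are skipped with a warning.
#'
#' @param run a [SampleRun-class].
#' @param proteins protein database ([Biostrings::AAStringSet] from
#'   [readProteinDb()] or [generateProteome()]).
#' @return data.frame with columns `accession`, `proteinLength`,
#'   `nPeptides`, `sumPeptideLengths`, `ratio`, one row per covered
#'   protein (sorted by accession).
#' @export
proteinCoverageRatio <- function(run, proteins) {
  stopifnot(is(run, "SampleRun"))
  if (any(Biostrings::width(proteins) == 0L))
    .stopf("invalid protein database: zero-length protein(s) present")
  pep <- peptideTable(run)
  plist <- as.list(pep$proteins)
  acc <- unlist(plist, use.names = FALSE)
  peplen <- rep(nchar(pep$sequence), lengths(plist))
  known <- acc %in% names(proteins)
  if (!all(known)) {
    .warnf("%d accession reference(s) not in the protein database; skipped (e.g. %s)",
           sum(!known), acc[!known][1L])
    acc <- acc[known]
    peplen <- peplen[known]
  }
  if (!length(acc))
    return(data.frame(accession = character(), proteinLength = integer(),
                      nPeptides = integer(), sumPeptideLengths = integer(),
                      ratio = numeric()))
  f <- factor(acc)
  sumLen <- as.integer(rowsum(peplen, f))
  nPep <- as.integer(table(f))
  accs <- levels(f)
  L <- Biostrings::width(proteins)[match(accs, names(proteins))]
  data.frame(accession = accs, proteinLength = L, nPeptides = nPep,
             sumPeptideLengths = sumLen, ratio = sumLen / L,
             stringsAsFactors = FALSE)
}

#' Calibrate the contaminant-flagging cutoff from clean reference runs
#'
#' Computes, for each clean run, the empirical 95th percentile of its
#' coverage-ratio distribution (linear-interpolation, quantile type 7) and
#' sets the cutoff to the arithmetic mean across runs. Runs covering fewer
#' than 20 proteins are excluded with a warning; if all runs are excluded
#' an error is raised.
#'
#' @param cleanRuns list of [SampleRun-class] objects regarded as free of
#'   proteolytic contamination (e.g. cell-line runs).
#' @param proteins protein database shared with the runs to be cleaned.
#' @return a [CutoffCalibration-class].
#' @export
calibrateCutoff <- function(cleanRuns, proteins) {
  if (is(cleanRuns, "SampleRun")) cleanRuns <- list(cleanRuns)
  if (!length(cleanRuns)) .stopf("at least one clean run required")
  ids <- character()
  pct <- numeric()
  for (run in cleanRuns) {
    cov <- proteinCoverageRatio(run, proteins)
    if (nrow(cov) < 20L) {
      .warnf("clean run %s covers only %d proteins (< 20); excluded from calibration",
             .runLabel(run), nrow(cov))
      next
    }
    ids <- c(ids, .runLabel(run))
    pct <- c(pct, unname(stats::quantile(cov$ratio, 0.95, type = 7)))
  }
  if (!length(ids))
    .stopf("no clean run with >= 20 covered proteins; cannot calibrate cutoff")
  new("CutoffCalibration", runIds = ids, percentiles = pct,
      cutoff = mean(pct), probs = 0.95)
}

#' Flag contaminant source proteins and curate a run
#'
#' Proteins whose coverage ratio exceeds the cutoff are flagged as likely
#' proteolytic-contamination sources. A peptide is removed only if *all*
#' of its source proteins are flagged (the conservative rule: a peptide
#' shared with an unflagged protein may still be a genuine ligand).
#' Applying the same cutoff twice is idempotent.
#'
#' @param run a [SampleRun-class].
#' @param proteins protein database.
#' @param cutoff positive coverage-ratio cutoff, typically
#'   `coverageCutoff(calibrateCutoff(...))`.
#' @return list with `run` (curated [SampleRun-class]), `report`
#'   (data.frame: coverage table plus `flagged` and `cutoffUsed` columns)
#'   and `removed` (character vector of removed peptide sequences).
#' @export
flagAndClean <- function(run, proteins, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    .stopf("cutoff must be a single positive number")
  cov <- suppressWarnings(proteinCoverageRatio(run, proteins))
  cov$flagged <- cov$ratio > cutoff
  cov$cutoffUsed <- cutoff
  flaggedAcc <- cov$accession[cov$flagged]
  pep <- peptideTable(run)
  plist <- as.list(pep$proteins)
  drop <- vapply(plist, function(p) {
    known <- p[p %in% names(proteins)]
    length(known) > 0L && all(known %in% flaggedAcc)
  }, logical(1))
  curated <- SampleRun(pep$sequence[!drop], proteins = plist[!drop],
                       intensity = pep$intensity[!drop],
                       sampleId = sampleId(run), replicateId = replicateId(run),
                       haplotype = haplotype(run),
                       tissueLabel = tissueLabel(run))
  list(run = curated, report = cov, removed = pep$sequence[drop])
}
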