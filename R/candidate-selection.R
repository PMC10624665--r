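#' Count runs containing each peptide
#'
#' @param peptides character vector of peptide sequences.
#' @param runs list of [SampleRun-class] objects.
#' @return integer vector: number of runs whose peptide set contains the
#'   exact sequence.
#' @export
replicateCount <- function(peptides, runs) {
  counts <- integer(length(peptides))
  for (r in runs) counts <- counts + (peptides %in% peptideSequences(r))
  counts
}

#' Select and rank candidate vaccine peptides
#'
#' Applies the selection pipeline to the union of peptides across runs:
#' (1) source gene upregulated, expression log fold change strictly above
#' `minLogFC`; (2) predicted binding affinity strictly below
#' `affinityMaxNM`; (3) peptide found in at least `minReplicates` runs.
#' The three filters are independent predicates, so the surviving set does
#' not depend on their order. Survivors are then ranked by a deterministic
#' total order: tissue priority (peptides observed in a
#' `prioritizeTissue` run first), preferred length first, ascending
#' affinity, descending replicate count, then sequence; the list is
#' truncated to `topK`. Each filter's survivor count is logged via
#' `message()` and attached as attribute `"filterLog"`.
#'
#' Peptides lacking a prediction, or (under `requireUpregulated`) lacking
#' a gene mapping or expression value, are excluded and counted, not
#' errors. Multi-gene peptides use the maximum log fold change among their
#' mapped genes.
#'
#' @param runs list of [SampleRun-class] objects.
#' @param predictions best-prediction data.frame (`peptide`, `allele`,
#'   `rank`, `affinityNM`, `class`), e.g. `predictBinding(...)$best`.
#' @param expression named numeric vector: gene -> log fold change.
#' @param peptideGeneMap data.frame with columns `peptide`, `gene`
#'   (repeated peptide rows allowed), or a named list peptide -> genes.
#' @param criteria a [CandidateCriteria-class] (default
#'   [candidateCriteria()]).
#' @param verbose emit the per-filter survivor log (default TRUE).
#' @return data.frame of candidate rows sorted by `finalRank`: `peptide`,
#'   `bestAllele`, `affinityNM`, `rank`, `nReplicates`, `genes`, `logFC`,
#'   `isPreferredLength`, `tissueEvidence`, `finalRank`.
#' @export
selectCandidates <- function(runs, predictions, expression, peptideGeneMap,
                             criteria = candidateCriteria(), verbose = TRUE) {
  stopifnot(is(criteria, "CandidateCriteria"))
  if (is.data.frame(peptideGeneMap)) {
    stopifnot(all(c("peptide", "gene") %in% colnames(peptideGeneMap)))
    geneMap <- split(as.character(peptideGeneMap$gene),
                     as.character(peptideGeneMap$peptide))
  } else {
    geneMap <- peptideGeneMap
  }
  pep <- unique(unlist(lapply(runs, peptideSequences), use.names = FALSE))
  logStep <- function(step, n) {
    if (verbose) message(sprintf("selectCandidates: %s -> %d peptide(s)", step, n))
    data.frame(step = step, survivors = n, stringsAsFactors = FALSE)
  }
  log <- logStep("input", length(pep))

  predIdx <- match(pep, predictions$peptide)
  hasPred <- !is.na(predIdx) & !is.na(predictions$affinityNM[predIdx])
  log <- rbind(log, logStep("with_prediction", sum(hasPred)))

  genes <- unname(geneMap[pep])
  logFC <- vapply(genes, function(g) {
    v <- expression[stats::na.omit(match(g, names(expression)))]
    if (length(v)) max(v) else NA_real_
  }, numeric(1))
  passFC <- if (criteria@requireUpregulated) {
    !is.na(logFC) & logFC > criteria@minLogFC
  } else rep(TRUE, length(pep))
  log <- rbind(log, logStep("upregulated", sum(hasPred & passFC)))

  affinity <- predictions$affinityNM[predIdx]
  passAff <- hasPred & affinity < criteria@affinityMaxNM
  log <- rbind(log, logStep("affinity", sum(hasPred & passFC & passAff)))

  nRep <- replicateCount(pep, runs)
  passRep <- nRep >= criteria@minReplicates
  keep <- hasPred & passFC & passAff & passRep
  log <- rbind(log, logStep("replicates", sum(keep)))

  tissueRuns <- if (!is.na(criteria@prioritizeTissue))
    Filter(function(r) tissueLabel(r) == criteria@prioritizeTissue, runs)
  else list()
  tissueHit <- if (length(tissueRuns)) replicateCount(pep, tissueRuns) > 0L
               else rep(FALSE, length(pep))

  out <- data.frame(
    peptide = pep,
    bestAllele = predictions$allele[predIdx],
    affinityNM = affinity,
    rank = predictions$rank[predIdx],
    nReplicates = nRep,
    genes = vapply(genes, function(g)
      paste(sort(unique(g)), collapse = ";"), character(1)),
    logFC = logFC,
    isPreferredLength = nchar(pep) == criteria@preferredLength,
    tissueEvidence = tissueHit,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]

  ord <- order(!out$tissueEvidence, !out$isPreferredLength, out$affinityNM,
               -out$nReplicates, out$peptide)
  out <- out[ord, , drop = FALSE]
  out <- utils::head(out, criteria@topK)
  out$finalRank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "filterLog") <- log
  attr(out, "criteria") <- criteria
  out
}

#' Export candidates as poly-lysine-extended sequences
#'
#' Prepends `k` lysines to each candidate (the "poly-K" format used for
#' electrostatic loading of peptides onto an adenovirus capsid). Peptides
#' that themselves start with K are flagged, since stripping `k` leading
#' lysines would not recover the original sequence unambiguously.
#'
#' @param candidates data.frame from [selectCandidates()] (any data.frame
#'   with a `peptide` column works).
#' @param k number of lysines to prepend (default 6; must be >= 1).
#' @param fastaPath optional path; when given, sequences are also written
#'   as FASTA (record ids `cand<rank>|<peptide>`).
#' @return data.frame with `peptide`, `polyK` and `startsWithK`.
#' @examples
#' exportPolyk <- exportPolyK(data.frame(peptide = "SIINFEKL"))
#' exportPolyk$polyK  # "KKKKKKSIINFEKL"
#' @export
exportPolyK <- function(candidates, k = 6L, fastaPath = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) .stopf("k must be >= 1")
  stopifnot("peptide" %in% colnames(candidates))
  pep <- candidates$peptide
  out <- data.frame(peptide = pep,
                    polyK = paste0(strrep("K", k), pep),
                    startsWithK = startsWith(pep, "K"),
                    stringsAsFactors = FALSE)
  if (!is.null(fastaPath)) {
    ids <- if ("finalRank" %in% colnames(candidates))
      sprintf("cand%d|%s", candidates$finalRank, pep)
    else sprintf("cand%d|%s", seq_along(pep), pep)
    seqs <- Biostrings::AAStringSet(out$polyK)
    names(seqs) <- ids
    Biostrings::writeXStringSet(seqs, fastaPath)
  }
  out
}
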