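#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom IRanges CharacterList
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' SampleRun: one immunopeptidomics replicate
#'
#' A `SampleRun` holds the unique eluted peptides observed in a single
#' immunopeptidomics run (one biological replicate of one sample) together
#' with the sample's MHC haplotype and a tissue label. Peptide sequences are
#' uppercase strings over the 20 canonical amino acids; duplicate sequences
#' are collapsed at construction (intensity aggregated by maximum, source
#' accessions by union), so a run is a set of unique peptides as in standard
#' ligandome reporting.
#'
#' @slot sampleId single character, sample label.
#' @slot replicateId single character, replicate label.
#' @slot peptides [S4Vectors::DataFrame] with columns `sequence` (character),
#'   `intensity` (numeric, `NA` when unmeasured) and `proteins`
#'   ([IRanges::CharacterList] of source protein accessions).
#' @slot haplotype character vector of canonical allele names (possibly
#'   empty; binding prediction requires a non-empty haplotype).
#' @slot tissueLabel one of `"tumor"`, `"benign"`, `"cell_line"`.
#'
#' @aliases SampleRun-class
#' @exportClass SampleRun
setClass("SampleRun",
  slots = c(
    sampleId = "character",
    replicateId = "character",
    peptides = "DataFrame",
    haplotype = "character",
    tissueLabel = "character"
  )
)

setValidity("SampleRun", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-NA string")
  if (length(object@replicateId) != 1L || is.na(object@replicateId))
    msg <- c(msg, "replicateId must be a single non-NA string")
  pep <- object@peptides
  need <- c("sequence", "intensity", "proteins")
  if (!all(need %in% colnames(pep))) {
    msg <- c(msg, sprintf("peptides must have columns %s",
                          paste(need, collapse = ", ")))
  } else {
    if (anyDuplicated(pep$sequence))
      msg <- c(msg, "peptide sequences must be unique within a run")
    if (length(pep$sequence) && !all(.isCanonicalSeq(pep$sequence)))
      msg <- c(msg, "peptide sequences must be uppercase canonical residues")
    if (any(!is.na(pep$intensity) & pep$intensity < 0))
      msg <- c(msg, "intensities must be non-negative")
  }
  if (length(object@tissueLabel) != 1L ||
      !object@tissueLabel %in% c("tumor", "benign", "cell_line"))
    msg <- c(msg, "tissueLabel must be one of tumor, benign, cell_line")
  if (length(msg)) msg else TRUE
})

#' Construct a SampleRun
#'
#' Collapses duplicate sequences (intensity by `max`, ignoring `NA`; source
#' accessions by union) and validates the result.
#'
#' @param sequences character vector of peptide sequences (uppercase,
#'   canonical alphabet).
#' @param proteins list of character vectors of source protein accessions,
#'   parallel to `sequences` (or a single [IRanges::CharacterList]).
#' @param intensity numeric vector of intensities (`NA` allowed).
#' @param sampleId,replicateId run labels.
#' @param haplotype character vector of allele names; normalized with
#'   [normalizeAllele()].
#' @param tissueLabel `"tumor"`, `"benign"` or `"cell_line"`.
#' @return a [SampleRun-class] object.
#' @examples
#' run <- SampleRun(c("SIINFEKL", "SIINFEKL"), intensity = c(10, 30),
#'                  sampleId = "s1", replicateId = "r1")
#' peptideTable(run)$intensity  # 30: duplicates collapse to the maximum
#' @export
SampleRun <- function(sequences,
                      proteins = NULL,
                      intensity = rep(NA_real_, length(sequences)),
                      sampleId = "sample",
                      replicateId = "rep1",
                      haplotype = character(),
                      tissueLabel = "cell_line") {
  sequences <- as.character(sequences)
  if (is.null(proteins))
    proteins <- rep(list(character()), length(sequences))
  if (is(proteins, "CharacterList")) proteins <- as.list(proteins)
  stopifnot(length(proteins) == length(sequences),
            length(intensity) == length(sequences))
  uniq <- unique(sequences)
  grp <- match(sequences, uniq)
  aggInt <- vapply(seq_along(uniq), function(i) {
    v <- intensity[grp == i]
    v <- v[!is.na(v)]
    if (length(v)) max(v) else NA_real_
  }, numeric(1))
  aggProt <- lapply(seq_along(uniq), function(i) {
    sort(unique(unlist(proteins[grp == i], use.names = FALSE)))
  })
  if (length(haplotype)) haplotype <- normalizeAllele(haplotype)
  new("SampleRun",
      sampleId = as.character(sampleId),
      replicateId = as.character(replicateId),
      peptides = DataFrame(sequence = uniq,
                           intensity = aggInt,
                           proteins = CharacterList(aggProt)),
      haplotype = haplotype,
      tissueLabel = tissueLabel)
}

#' PssmModel: per-allele position-specific scoring matrix
#'
#' Log-odds matrices (one per supported peptide length, lengths within 8-13)
#' against a background residue distribution. Entry `[i, a]` is
#' `log(((count[i,a] + pc * bg[a]) / (N + pc)) / bg[a])` for `N` training
#' binders and pseudocount `pc`; a peptide's score is the sum of its
#' positional entries.
#'
#' @slot allele canonical allele name.
#' @slot matrices named list (names = lengths as characters) of numeric
#'   matrices with 20 columns in [AA20] order.
#' @slot background named numeric vector of 20 strictly positive residue
#'   frequencies summing to 1.
#' @slot pseudocount positive numeric.
#' @aliases PssmModel-class
#' @exportClass PssmModel
setClass("PssmModel",
  slots = c(
    allele = "character",
    matrices = "list",
    background = "numeric",
    pseudocount = "numeric"
  )
)

setValidity("PssmModel", function(object) {
  msg <- character()
  if (length(object@allele) != 1L)
    msg <- c(msg, "allele must be a single name")
  if (length(object@background) != 20L ||
      any(object@background <= 0) ||
      abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background must be 20 strictly positive frequencies summing to 1")
  lens <- suppressWarnings(as.integer(names(object@matrices)))
  if (length(object@matrices) == 0L)
    msg <- c(msg, "at least one length matrix required")
  if (anyNA(lens) || !all(lens %in% 8:13))
    msg <- c(msg, "supported lengths must be within 8..13")
  for (i in seq_along(object@matrices)) {
    m <- object@matrices[[i]]
    if (!is.matrix(m) || ncol(m) != 20L || nrow(m) != lens[i])
      msg <- c(msg, sprintf("matrix for length %s must be %s x 20",
                            names(object@matrices)[i], names(object@matrices)[i]))
  }
  if (length(object@pseudocount) != 1L || object@pseudocount <= 0)
    msg <- c(msg, "pseudocount must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' RankCalibration: empirical background score distribution for one allele
#'
#' Sorted scores of `nBackground` random background peptides per supported
#' length; rank percentiles and score quantiles are read off this sample.
#'
#' @slot allele allele name.
#' @slot scores named list (by length) of ascending-sorted numeric vectors.
#' @slot nBackground integer, background sample size per length (>= 1000).
#' @slot seed integer seed used for the background draw.
#' @aliases RankCalibration-class
#' @exportClass RankCalibration
setClass("RankCalibration",
  slots = c(
    allele = "character",
    scores = "list",
    nBackground = "integer",
    seed = "integer"
  )
)

setValidity("RankCalibration", function(object) {
  msg <- character()
  if (object@nBackground < 1000L)
    msg <- c(msg, "nBackground must be >= 1000")
  for (s in object@scores)
    if (is.unsorted(s)) msg <- c(msg, "background scores must be sorted ascending")
  if (length(msg)) msg else TRUE
})

#' PssmPredictor: PSSM models plus rank calibrations for a haplotype
#'
#' The built-in binding-prediction backend: one [PssmModel-class] and one
#' [RankCalibration-class] per allele. Use [pssmPredictor()] to build and
#' [predictBinding()] to query.
#'
#' @slot models named list of [PssmModel-class], names = allele.
#' @slot calibrations named list of [RankCalibration-class], names = allele.
#' @aliases PssmPredictor-class
#' @exportClass PssmPredictor
setClass("PssmPredictor",
  slots = c(models = "list", calibrations = "list")
)

setValidity("PssmPredictor", function(object) {
  if (!identical(names(object@models), names(object@calibrations)))
    return("models and calibrations must cover the same alleles")
  TRUE
})

#' OverlapMatrix: pairwise peptide-set overlap percentages
#'
#' Raw (uncapped) pairwise overlap percentages between samples, plus the cap
#' used for rendering. In `smaller_set` mode the entry for samples A, B is
#' `100 * |A n B| / min(|A|, |B|)` (Szymkiewicz-Simpson, symmetric); in
#' `row_set` mode it is `100 * |A n B| / |A|` per row. Capping applies only
#' to the rendered copy returned by `overlapValues(x, capped = TRUE)`.
#'
#' @slot samples character vector of sample ids (row/column order).
#' @slot values numeric matrix of raw percentages.
#' @slot cap percentage cap used for display (default 40).
#' @slot mode `"smaller_set"` or `"row_set"`.
#' @aliases OverlapMatrix-class
#' @exportClass OverlapMatrix
setClass("OverlapMatrix",
  slots = c(samples = "character", values = "matrix",
            cap = "numeric", mode = "character")
)

setValidity("OverlapMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != length(object@samples) || ncol(v) != length(object@samples))
    msg <- c(msg, "values must be a square matrix over the samples")
  if (any(v < -1e-9 | v > 100 + 1e-9))
    msg <- c(msg, "overlap percentages must lie in [0, 100]")
  if (!object@mode %in% c("smaller_set", "row_set"))
    msg <- c(msg, "mode must be smaller_set or row_set")
  if (object@mode == "smaller_set") {
    if (max(abs(v - t(v))) > 1e-9)
      msg <- c(msg, "smaller_set overlap matrix must be symmetric")
    if (any(abs(diag(v) - 100) > 1e-9))
      msg <- c(msg, "diagonal must be 100 before capping")
  }
  if (length(msg)) msg else TRUE
})

#' CutoffCalibration: clean-run-derived coverage-ratio cutoff
#'
#' Stores, for each clean reference run, the empirical 95th percentile of
#' its protein coverage-ratio distribution; the contaminant-flagging cutoff
#' is the arithmetic mean of those percentiles.
#'
#' @slot runIds run labels contributing to the calibration.
#' @slot percentiles per-run 95th-percentile values (type-7 quantile).
#' @slot cutoff mean of `percentiles`.
#' @slot probs the percentile level used (0.95).
#' @aliases CutoffCalibration-class
#' @exportClass CutoffCalibration
setClass("CutoffCalibration",
  slots = c(runIds = "character", percentiles = "numeric",
            cutoff = "numeric", probs = "numeric")
)

setValidity("CutoffCalibration", function(object) {
  if (length(object@percentiles) != length(object@runIds))
    return("one percentile per run required")
  if (abs(object@cutoff - mean(object@percentiles)) > 1e-12)
    return("cutoff must equal the arithmetic mean of the per-run percentiles")
  TRUE
})

#' CandidateCriteria: thresholds of the antigen selection pipeline
#'
#' Defaults follow the published mesothelioma selection pipeline: predicted
#' binding affinity below 50 nM (strict), expression log fold change above 2
#' (strict), identification in at least 3 replicates, and preference for
#' 9mers during ranking.
#'
#' @slot affinityMaxNM affinity ceiling in nM (strict `<`).
#' @slot minLogFC expression log fold-change floor (strict `>`).
#' @slot minReplicates minimum number of runs containing the peptide (`>=`).
#' @slot preferredLength peptide length favored in ranking.
#' @slot topK number of candidates to retain.
#' @slot requireUpregulated whether filter (1) applies.
#' @slot prioritizeTissue optional tissue label whose peptides rank first
#'   (`NA` to disable).
#' @aliases CandidateCriteria-class
#' @exportClass CandidateCriteria
setClass("CandidateCriteria",
  slots = c(affinityMaxNM = "numeric", minLogFC = "numeric",
            minReplicates = "integer", preferredLength = "integer",
            topK = "integer", requireUpregulated = "logical",
            prioritizeTissue = "character")
)

setValidity("CandidateCriteria", function(object) {
  msg <- character()
  if (object@affinityMaxNM <= 0) msg <- c(msg, "affinityMaxNM must be positive")
  if (object@minReplicates < 1L) msg <- c(msg, "minReplicates must be >= 1")
  if (object@preferredLength < 1L) msg <- c(msg, "preferredLength must be >= 1")
  if (object@topK < 1L) msg <- c(msg, "topK must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname CandidateCriteria-class
#' @param affinityMaxNM,minLogFC,minReplicates,preferredLength,topK,requireUpregulated,prioritizeTissue
#'   see the corresponding slots.
#' @return a `CandidateCriteria` object.
#' @export
candidateCriteria <- function(affinityMaxNM = 50, minLogFC = 2,
                              minReplicates = 3L, preferredLength = 9L,
                              topK = 15L, requireUpregulated = TRUE,
                              prioritizeTissue = NA_character_) {
  new("CandidateCriteria",
      affinityMaxNM = affinityMaxNM, minLogFC = minLogFC,
      minReplicates = as.integer(minReplicates),
      preferredLength = as.integer(preferredLength),
      topK = as.integer(topK),
      requireUpregulated = requireUpregulated,
      prioritizeTissue = as.character(prioritizeTissue))
}
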