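#' Peptide length distribution of a run
#'
#' Counts unique peptides per length and reports three summary fractions
#' used on the QC dashboard: the percentage of peptides within the MHC
#' class I window (8-13mers), the percentage of 9mers among all peptides,
#' and the percentage of 9mers within the 8-13 window. An eluted ligandome
#' of good quality peaks sharply at 9 residues.
#'
#' @param run a [SampleRun-class] with at least one peptide.
#' @return list with elements `runId`, `table` (data.frame: `length`,
#'   `count`, `percentage`; percentages over observed lengths sum to 100),
#'   `fraction8to13`, `fraction9OfAll`, `fraction9Of8to13` (percent).
#' @export
lengthDistribution <- function(run) {
  stopifnot(is(run, "SampleRun"))
  if (nPeptides(run) == 0L) .stopf("run %s is empty", .runLabel(run))
  lens <- nchar(peptideSequences(run))
  tab <- table(lens)
  counts <- as.integer(tab)
  lengths <- as.integer(names(tab))
  n <- length(lens)
  n9 <- sum(lens == 9L)
  n813 <- sum(lens >= 8L & lens <= 13L)
  list(runId = .runLabel(run),
       table = data.frame(length = lengths, count = counts,
                          percentage = 100 * counts / n),
       fraction8to13 = 100 * n813 / n,
       fraction9OfAll = 100 * n9 / n,
       fraction9Of8to13 = if (n813) 100 * n9 / n813 else NA_real_)
}

#' Fraction of predicted MHC binders in a run
#'
#' Percentage of peptides (within the chosen length scope) whose best-
#' allele rank percentile across the run's haplotype is below 2 — i.e. the
#' peptide is a predicted strong or weak binder. Peptides not covered by
#' any allele model count as non-binders.
#'
#' @param run a [SampleRun-class] with non-empty haplotype.
#' @param predictor a [PssmPredictor-class].
#' @param scope `"all_8_13"` (default) or `"only_9"`.
#' @return percent (numeric scalar); `NA` when no peptide falls in scope.
#' @export
binderFraction <- function(run, predictor, scope = c("all_8_13", "only_9")) {
  scope <- match.arg(scope)
  if (!length(haplotype(run)))
    .stopf("run %s has no haplotype; binding prediction impossible",
           .runLabel(run))
  seqs <- peptideSequences(run)
  lens <- nchar(seqs)
  sel <- if (scope == "only_9") lens == 9L else lens >= 8L & lens <= 13L
  if (!any(sel)) return(NA_real_)
  al <- intersect(alleles(predictor), haplotype(run))
  if (!length(al))
    .stopf("predictor has no model for any allele of run %s", .runLabel(run))
  best <- suppressWarnings(predictBinding(predictor, seqs[sel], al))$best
  100 * mean(!is.na(best$rank) & best$rank < 2)
}

#' Deconvolute allele specificity of a run's peptides
#'
#' Assigns every peptide (within the length scope) its best predicted
#' allele and binder class, and tallies the stacked-bar composition: per
#' allele the number of strong and weak binders, plus overall non-binder
#' and unassignable counts.
#'
#' @param run a [SampleRun-class] with non-empty haplotype.
#' @param predictor a [PssmPredictor-class].
#' @param lengths integer vector of peptide lengths to consider (default 9,
#'   the dashboard convention; use `8:13` for the full class I window).
#' @return list with `composition` (data.frame: `allele`, `SB`, `WB`),
#'   `nB` (count of non-binders), `unassignable` (count with no covering
#'   allele), `assignments` (per-peptide data.frame), `runId`.
#' @export
deconvoluteSpecificity <- function(run, predictor, lengths = 9L) {
  if (!length(haplotype(run)))
    .stopf("run %s has no haplotype", .runLabel(run))
  seqs <- peptideSequences(run)
  seqs <- seqs[nchar(seqs) %in% lengths]
  if (!length(seqs)) .stopf("no peptides of length %s in run %s",
                            paste(lengths, collapse = ","), .runLabel(run))
  al <- intersect(alleles(predictor), haplotype(run))
  if (!length(al)) .stopf("predictor covers no allele of run %s", .runLabel(run))
  best <- suppressWarnings(predictBinding(predictor, seqs, al))$best
  bound <- best$class %in% c("SB", "WB")
  comp <- data.frame(allele = sort(al), SB = 0L, WB = 0L)
  if (any(bound)) {
    t2 <- table(factor(best$allele[bound], levels = comp$allele),
                factor(best$class[bound], levels = c("SB", "WB")))
    comp$SB <- as.integer(t2[, "SB"])
    comp$WB <- as.integer(t2[, "WB"])
  }
  unas <- sum(best$allele == "none")
  list(runId = .runLabel(run),
       composition = comp,
       nB = sum(!bound) - unas,
       unassignable = unas,
       assignments = cbind(best, length = nchar(best$peptide)))
}

#' Exclusive replicate-overlap sets (UpSet semantics)
#'
#' For every non-empty subset of runs, the number of peptides found in
#' exactly that subset (each peptide counted once, in the subset of runs
#' containing it). Exclusive sizes sum to the size of the union.
#'
#' @param runs list of >= 2 [SampleRun-class] objects.
#' @return data.frame with columns `subset` (run labels joined by `"&"`),
#'   `degree` (subset size) and `size` (exclusive intersection size),
#'   covering all non-empty subsets.
#' @export
replicateOverlapSets <- function(runs) {
  if (length(runs) < 2L) .stopf("at least 2 runs required for overlap sets")
  if (length(runs) > 15L) .stopf("too many runs for exhaustive subsets")
  labels <- vapply(runs, .runLabel, character(1))
  if (anyDuplicated(labels)) .stopf("duplicate run labels: %s",
                                    paste(labels[duplicated(labels)], collapse = ", "))
  sets <- lapply(runs, peptideSequences)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1L)
  pattern <- apply(member, 1L, function(b) paste(labels[b], collapse = "&"))
  observed <- table(pattern)
  k <- length(runs)
  combos <- unlist(lapply(seq_len(k), function(d)
    utils::combn(seq_len(k), d, function(i)
      paste(labels[i], collapse = "&"), simplify = FALSE)),
    recursive = FALSE)
  subset <- unlist(combos)
  size <- integer(length(subset))
  hit <- match(subset, names(observed))
  size[!is.na(hit)] <- as.integer(observed[hit[!is.na(hit)]])
  data.frame(subset = subset,
             degree = lengths(strsplit(subset, "&", fixed = TRUE)),
             size = size, stringsAsFactors = FALSE)
}

#' Positional residue frequencies and information content per allele group
#'
#' Summarizes predictor-assigned peptide groups as sequence motifs: a
#' column-stochastic residue frequency matrix (20 rows in [AA20] order, one
#' column per position) and per-position information content
#' `log2(20) - H` in bits, where `H` is the Shannon entropy of the column.
#' Groups with fewer than 10 peptides of the requested length are reported
#' as insufficient.
#'
#' @param groups named list of peptide character vectors (e.g. per-allele
#'   assignments from [deconvoluteSpecificity()]).
#' @param length peptide length to summarize (default 9).
#' @return named list; each element is either
#'   `list(freq = <20 x length matrix>, informationContent = <numeric>,
#'   n = <int>)` or `list(insufficient = TRUE, n = <int>)`.
#' @export
motifSummary <- function(groups, length = 9L) {
  stopifnot(is.list(groups))
  lapply(groups, function(peps) {
    peps <- peps[nchar(peps) == length]
    n <- base::length(peps)
    if (n < 10L) return(list(insufficient = TRUE, n = n))
    idx <- .peptideIndexMatrix(peps, length)
    counts <- apply(idx, 1L, tabulate, nbins = 20L)  # 20 x length
    freq <- sweep(counts, 2L, colSums(counts), `/`)
    rownames(freq) <- AA20
    ic <- apply(freq, 2L, function(f) {
      f <- f[f > 0]
      log2(20) + sum(f * log2(f))
    })
    list(freq = freq, informationContent = ic, n = n)
  })
}
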