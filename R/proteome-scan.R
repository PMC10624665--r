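#' Enumerate all 9mer windows of a protein subset
#'
#' Sliding window of width 9, stride 1: a protein of length L yields
#' `max(0, L - 8)` windows. Duplicate 9mers arising from different
#' proteins (or repeated windows) are merged with the union of their
#' source accessions.
#'
#' @param proteins protein database ([Biostrings::AAStringSet]).
#' @param subset accessions to scan (default: all). Unknown accessions
#'   raise an error.
#' @return [S4Vectors::DataFrame] with columns `peptide` (unique 9mers,
#'   sorted) and `sources` ([IRanges::CharacterList]).
#' @export
scan9mers <- function(proteins, subset = names(proteins)) {
  miss <- setdiff(subset, names(proteins))
  if (length(miss)) .stopf("accession(s) not in protein database: %s",
                           paste(miss, collapse = ", "))
  subset <- unique(subset)
  seqs <- as.character(proteins[subset])
  Ls <- nchar(seqs)
  nwin <- pmax(0L, Ls - 8L)
  keep <- nwin > 0L
  if (!any(keep))
    return(DataFrame(peptide = character(), sources = CharacterList()))
  windows <- unlist(lapply(which(keep), function(i)
    substring(seqs[i], seq_len(nwin[i]), seq_len(nwin[i]) + 8L)),
    use.names = FALSE)
  acc <- rep(subset[keep], nwin[keep])
  bySeq <- split(acc, windows)  # sorted unique peptides
  DataFrame(peptide = names(bySeq),
            sources = CharacterList(lapply(bySeq, function(a) sort(unique(a)))))
}

#' Scan a proteome and predict presentation across a haplotype
#'
#' Generates the in-silico predicted-presentation dataset: all 9mers of
#' the selected proteins (by default, every protein with at least one
#' eluted peptide in `runs`), predicted across the haplotype, annotated
#' with whether and in how many immunopeptidomics runs each 9mer was
#' actually observed.
#'
#' @param proteins protein database.
#' @param predictor a [PssmPredictor-class].
#' @param runs list of [SampleRun-class] objects (may be empty).
#' @param subset accessions to scan; default: accessions carrying >= 1
#'   eluted peptide across `runs` (all proteins when no runs are given).
#' @param alleles alleles to use (default: all of the predictor's).
#' @return data.frame with columns `peptide`, `sources` (`;`-joined),
#'   one `rank_<allele>` column per allele, `bestAllele`, `bestRank`,
#'   `class`, `observed`, `nRunsObserved`.
#' @export
scanProteome <- function(proteins, predictor, runs = list(),
                         subset = NULL, alleles = NULL) {
  if (is.null(subset)) {
    subset <- if (length(runs)) {
      eluted <- unique(unlist(lapply(runs, function(r)
        unlist(as.list(peptideTable(r)$proteins), use.names = FALSE)),
        use.names = FALSE))
      intersect(names(proteins), eluted)
    } else names(proteins)
  }
  if (!length(subset)) .stopf("no proteins selected for scanning")
  scan <- scan9mers(proteins, subset)
  if (!nrow(scan)) .stopf("selected proteins yield no 9mer windows")
  pred <- suppressWarnings(predictBinding(predictor, scan$peptide, alleles))
  out <- data.frame(peptide = scan$peptide,
                    sources = vapply(as.list(scan$sources), paste,
                                     character(1), collapse = ";"),
                    stringsAsFactors = FALSE)
  for (al in unique(pred$perAllele$allele)) {
    sub <- pred$perAllele[pred$perAllele$allele == al, ]
    out[[paste0("rank_", al)]] <- sub$rank[match(out$peptide, sub$peptide)]
  }
  out$bestAllele <- pred$best$allele
  out$bestRank <- pred$best$rank
  out$class <- pred$best$class
  counts <- integer(nrow(out))
  for (r in runs) counts <- counts + (out$peptide %in% peptideSequences(r))
  out$nRunsObserved <- counts
  out$observed <- counts >= 1L
  out
}

#' Compare predicted strong binders with observed elution
#'
#' Among all scanned 9mers, counts the predicted strong binders
#' (best rank <= 0.5, the inclusive convention used when reporting
#' predicted datasets; the SB *class* boundary is strict) and the fraction
#' of them observed in at least one run.
#'
#' @param scan data.frame from [scanProteome()].
#' @return list with `nScanned`, `nStrong`, `nStrongObserved`, `fraction`
#'   (`NA` when no strong binders) and `observedNotStrong`.
#' @export
predictedVsObserved <- function(scan) {
  stopifnot(all(c("bestRank", "observed") %in% colnames(scan)))
  strong <- !is.na(scan$bestRank) & scan$bestRank <= 0.5
  nStrong <- sum(strong)
  list(nScanned = nrow(scan),
       nStrong = nStrong,
       nStrongObserved = sum(strong & scan$observed),
       fraction = if (nStrong) sum(strong & scan$observed) / nStrong
                  else NA_real_,
       observedNotStrong = sum(scan$observed & !strong))
}

#' Presentation-versus-abundance association statistics
#'
#' Three planned comparisons relating presentation to protein abundance
#' and prediction: (1) a two-sided Mann-Whitney (Wilcoxon rank-sum) test
#' comparing the abundance of proteins that present at least one peptide
#' in the runs against proteins that present none; (2) the Spearman
#' correlation of per-peptide mean intensity with the number of runs in
#' which the peptide was observed; (3) the Spearman correlation of best
#' binding rank with the number of runs observed (requires
#' `predictions`). No multiple-testing correction is applied (single
#' planned comparisons). Degenerate constant vectors yield `NA`
#' correlations.
#'
#' @param abundance named numeric vector: accession -> abundance.
#' @param runs list of [SampleRun-class] objects.
#' @param predictions optional best-prediction data.frame (from
#'   `predictBinding()$best`) covering the runs' peptides.
#' @return list with `wilcox` (statistic, p.value, nPresented,
#'   nNotPresented), `intensityVsRuns` and `rankVsRuns` (each rho, n).
#' @export
presentationAbundanceStats <- function(abundance, runs, predictions = NULL) {
  stopifnot(!is.null(names(abundance)))
  presentedAcc <- unique(unlist(lapply(runs, function(r)
    unlist(as.list(peptideTable(r)$proteins), use.names = FALSE)),
    use.names = FALSE))
  isPres <- names(abundance) %in% presentedAcc
  if (sum(isPres) < 10L || sum(!isPres) < 10L)
    .stopf("need >= 10 proteins in each group (presented: %d, not: %d)",
           sum(isPres), sum(!isPres))
  wt <- stats::wilcox.test(abundance[isPres], abundance[!isPres],
                           alternative = "two.sided", exact = FALSE)

  # per-peptide replicate counts and mean intensities across runs
  allPep <- unique(unlist(lapply(runs, peptideSequences), use.names = FALSE))
  nRuns <- integer(length(allPep))
  sumInt <- numeric(length(allPep))
  nInt <- integer(length(allPep))
  for (r in runs) {
    pep <- peptideTable(r)
    m <- match(pep$sequence, allPep)
    nRuns[m] <- nRuns[m] + 1L
    has <- !is.na(pep$intensity)
    sumInt[m[has]] <- sumInt[m[has]] + pep$intensity[has]
    nInt[m[has]] <- nInt[m[has]] + 1L
  }
  meanInt <- ifelse(nInt > 0L, sumInt / pmax(nInt, 1L), NA_real_)
  intCor <- .safeSpearman(meanInt, nRuns)

  rankCor <- list(rho = NA_real_, n = 0L)
  if (!is.null(predictions)) {
    m <- match(allPep, predictions$peptide)
    ok <- !is.na(m) & !is.na(predictions$rank[m])
    rankCor <- .safeSpearman(predictions$rank[m[ok]], nRuns[ok])
  }
  list(wilcox = list(statistic = unname(wt$statistic),
                     p.value = wt$p.value,
                     nPresented = sum(isPres),
                     nNotPresented = sum(!isPres)),
       intensityVsRuns = intCor,
       rankVsRuns = rankCor)
}

.safeSpearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(rho = NA_real_, n = sum(ok)))
  list(rho = unname(stats::cor(x[ok], y[ok], method = "spearman")),
       n = sum(ok))
}
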