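#' Build the PSSM-based binding predictor backend
#'
#' Bundles one [PssmModel-class] per allele with a Monte-Carlo
#' [RankCalibration-class] (see [calibrateRanks()]). The calibration seed
#' and background sample size are recorded in the object so every rank is
#' reproducible.
#'
#' @param models list of [PssmModel-class] objects (one per allele).
#' @param nBackground background sample size per length (default 100000).
#' @param seed integer seed for calibration.
#' @return a [PssmPredictor-class].
#' @export
pssmPredictor <- function(models, nBackground = 100000L, seed = 1L) {
  if (is(models, "PssmModel")) models <- list(models)
  names(models) <- vapply(models, function(m) m@allele, character(1))
  if (anyDuplicated(names(models)))
    .stopf("duplicate allele models: %s",
           paste(names(models)[duplicated(names(models))], collapse = ", "))
  calibs <- lapply(models, calibrateRanks, nBackground = nBackground,
                   seed = seed)
  new("PssmPredictor", models = models, calibrations = calibs)
}

#' Classify rank percentiles into binder classes
#'
#' Strong binders (SB) rank below 0.5, weak binders (WB) rank between 0.5
#' and 2 (inclusive), non-binders (nB) above 2. `NA` ranks (no allele model
#' covers the peptide length) are classified nB.
#'
#' @param rank numeric vector of rank percentiles in \[0, 100\].
#' @return character vector of `"SB"`, `"WB"`, `"nB"`.
#' @examples
#' binderClass(c(0.3, 1.5, 5))  # "SB" "WB" "nB"
#' @export
binderClass <- function(rank) {
  out <- rep("nB", length(rank))
  out[!is.na(rank) & rank < 0.5] <- "SB"
  out[!is.na(rank) & rank >= 0.5 & rank <= 2] <- "WB"
  out
}

#' Predict peptide-MHC binding across a haplotype
#'
#' Scores each peptide against every requested allele, converts scores to
#' empirical rank percentiles and to a surrogate affinity
#' `50000^(1 - s)` nM, where `s` is the peptide's score quantile within the
#' allele's calibration sample (monotone decreasing in score, in
#' (0, 50000\] nM). The best allele per peptide is the one with minimal
#' rank; ties break to the lexicographically first allele name. Alleles
#' whose models do not cover a peptide's length are skipped with a warning;
#' a peptide covered by no allele is returned unassignable (allele
#' `"none"`, rank `NA`, class `"nB"`).
#'
#' @param predictor a [PssmPredictor-class].
#' @param peptides character vector of peptide sequences.
#' @param alleles subset of `alleles(predictor)` to use (default all).
#' @return list with elements `best` (data.frame: `peptide`, `allele`,
#'   `rank`, `affinityNM`, `class`, one row per peptide in input order) and
#'   `perAllele` (long data.frame over peptide x allele pairs scored).
#' @export
predictBinding <- function(predictor, peptides, alleles = NULL) {
  stopifnot(is(predictor, "PssmPredictor"))
  if (is.null(alleles)) alleles <- alleles(predictor)
  miss <- setdiff(alleles, names(predictor@models))
  if (length(miss))
    .stopf("no model for allele(s): %s", paste(miss, collapse = ", "))
  peptides <- as.character(peptides)
  lens <- nchar(peptides)
  perAllele <- list()
  for (al in sort(alleles)) {
    model <- predictor@models[[al]]
    calib <- predictor@calibrations[[al]]
    supp <- supportedLengths(model)
    sel <- which(lens %in% supp)
    if (length(sel) < length(peptides))
      .warnf("allele %s skipped for %d peptide(s) with unsupported length",
             al, length(peptides) - length(sel))
    if (!length(sel)) next
    rank <- numeric(length(sel))
    qq <- numeric(length(sel))
    for (L in unique(lens[sel])) {
      ii <- which(lens[sel] == L)
      sc <- scorePeptides(
        new("PssmModel", allele = al,
            matrices = model@matrices[as.character(L)],
            background = model@background, pseudocount = model@pseudocount),
        peptides[sel][ii])
      bg <- calib@scores[[as.character(L)]]
      rank[ii] <- .rankFromScores(bg, sc)
      qq[ii] <- .quantileFromScores(bg, sc)
    }
    perAllele[[al]] <- data.frame(
      peptide = peptides[sel], allele = al, rank = rank,
      affinityNM = 50000 ^ (1 - qq), stringsAsFactors = FALSE)
  }
  long <- if (length(perAllele)) do.call(rbind, perAllele) else
    data.frame(peptide = character(), allele = character(),
               rank = numeric(), affinityNM = numeric())
  rownames(long) <- NULL
  long$class <- binderClass(long$rank)

  best <- data.frame(peptide = peptides, allele = "none",
                     rank = NA_real_, affinityNM = NA_real_,
                     class = "nB", stringsAsFactors = FALSE)
  if (nrow(long)) {
    # alleles were processed in sorted order, so within a peptide the stable
    # minimum breaks ties to the lexicographically first allele
    ord <- order(match(long$peptide, peptides), long$rank)
    srt <- long[ord, ]
    first <- srt[!duplicated(srt$peptide), ]
    # peptides may repeat in the input; assign every occurrence
    for (col in c("allele", "rank", "affinityNM", "class")) {
      idx <- match(best$peptide, first$peptide)
      hit <- !is.na(idx)
      best[[col]][hit] <- first[[col]][idx[hit]]
    }
  }
  list(best = best, perAllele = long)
}
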