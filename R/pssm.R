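#' Build a position-specific scoring matrix from aligned binders
#'
#' Computes pseudocount-regularized log-odds against a background residue
#' distribution. For `N` binders with residue counts `count[i, a]` at
#' position `i`, the matrix entry is
#' `log(((count[i, a] + pseudocount * background[a]) / (N + pseudocount)) / background[a])`.
#' With counts proportional to the background the entry is 0, so a fully
#' uninformative matrix scores every peptide 0.
#'
#' @param binders character vector of >= 10 equal-length sequences (length
#'   within 8-13, canonical alphabet).
#' @param pseudocount positive smoothing mass (default 1).
#' @param background named numeric vector of 20 residue frequencies in
#'   [AA20] order (default uniform 1/20).
#' @param allele allele name recorded in the model.
#' @return a [PssmModel-class] supporting the single training length.
#' @examples
#' set.seed(1)
#' binders <- vapply(1:20, function(i)
#'   paste(sample(ipQC::AA20, 9, TRUE), collapse = ""), character(1))
#' m <- buildPssm(binders, allele = "A02:01")
#' supportedLengths(m)
#' @export
buildPssm <- function(binders, pseudocount = 1,
                      background = uniformBackground(),
                      allele = "synthetic") {
  binders <- as.character(binders)
  if (length(binders) == 0L) .stopf("no binder sequences supplied")
  lens <- nchar(binders)
  if (length(unique(lens)) != 1L)
    .stopf("binder sequences must all have the same length (got %s)",
           paste(sort(unique(lens)), collapse = ", "))
  L <- lens[1L]
  if (!L %in% 8:13) .stopf("supported peptide lengths are 8..13, got %d", L)
  if (length(binders) < 10L)
    .stopf("at least 10 binder sequences required, got %d", length(binders))
  if (!all(.isCanonicalSeq(binders)))
    .stopf("binder sequences must use the canonical 20-letter alphabet")
  background <- .checkBackground(background)
  idx <- .peptideIndexMatrix(binders, L)
  counts <- t(apply(idx, 1L, tabulate, nbins = 20L))
  N <- length(binders)
  freq <- sweep(counts, 2L, pseudocount * background, `+`) / (N + pseudocount)
  mat <- log(sweep(freq, 2L, background, `/`))
  dimnames(mat) <- list(NULL, AA20)
  new("PssmModel", allele = allele,
      matrices = stats::setNames(list(mat), as.character(L)),
      background = background, pseudocount = pseudocount)
}

#' Uniform background residue distribution
#'
#' @return named numeric vector: 1/20 for each canonical residue.
#' @export
uniformBackground <- function() {
  stats::setNames(rep(1 / 20, 20L), AA20)
}

#' Background residue frequencies from a proteome
#'
#' Empirical residue frequencies over all sequences of a protein database,
#' an alternative to the uniform default.
#'
#' @param proteins a named [Biostrings::AAStringSet].
#' @return named numeric vector of 20 frequencies summing to 1.
#' @export
proteomeBackground <- function(proteins) {
  counts <- colSums(Biostrings::letterFrequency(proteins, AA20))
  freq <- counts / sum(counts)
  # keep strictly positive frequencies: tiny floor for absent residues
  if (any(freq == 0)) {
    freq <- freq + 1e-6
    freq <- freq / sum(freq)
  }
  stats::setNames(as.numeric(freq), AA20)
}

.checkBackground <- function(background) {
  if (length(background) != 20L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9)
    .stopf("background must be 20 strictly positive frequencies summing to 1")
  if (is.null(names(background))) names(background) <- AA20
  background[AA20]
}

#' Merge per-length PSSMs of the same allele into one model
#'
#' @param ... [PssmModel-class] objects for the same allele (distinct
#'   lengths) built against the same background.
#' @return a [PssmModel-class] covering the union of lengths.
#' @export
mergePssm <- function(...) {
  models <- list(...)
  if (length(models) == 1L && is.list(models[[1L]])) models <- models[[1L]]
  stopifnot(length(models) >= 1L)
  allele <- unique(vapply(models, function(m) m@allele, character(1)))
  if (length(allele) != 1L)
    .stopf("cannot merge models for different alleles: %s",
           paste(allele, collapse = ", "))
  mats <- do.call(c, lapply(models, function(m) m@matrices))
  if (anyDuplicated(names(mats)))
    .stopf("duplicate length matrices while merging models for %s", allele)
  new("PssmModel", allele = allele, matrices = mats[order(as.integer(names(mats)))],
      background = models[[1L]]@background,
      pseudocount = models[[1L]]@pseudocount)
}

#' Score peptides against a PSSM
#'
#' A peptide's score is the sum over positions of its log-odds entries.
#'
#' @param model a [PssmModel-class].
#' @param peptides character vector; every length must be supported by the
#'   model, otherwise an error is raised.
#' @return numeric vector of scores.
#' @export
scorePeptides <- function(model, peptides) {
  peptides <- as.character(peptides)
  lens <- nchar(peptides)
  bad <- !lens %in% supportedLengths(model)
  if (any(bad))
    .stopf("peptide length(s) %s not supported by the %s model",
           paste(sort(unique(lens[bad])), collapse = ", "), model@allele)
  out <- numeric(length(peptides))
  for (L in unique(lens)) {
    sel <- which(lens == L)
    mat <- model@matrices[[as.character(L)]]
    idx <- .peptideIndexMatrix(peptides[sel], L)
    sc <- numeric(length(sel))
    for (i in seq_len(L)) sc <- sc + mat[i, idx[i, ]]
    out[sel] <- sc
  }
  out
}

# scores of n random background peptides of length L (index sampling; no
# string materialization needed)
.backgroundScores <- function(mat, background, n) {
  L <- nrow(mat)
  idx <- matrix(sample.int(20L, n * L, replace = TRUE, prob = background),
                nrow = L)
  sc <- numeric(n)
  for (i in seq_len(L)) sc <- sc + mat[i, idx[i, ]]
  sc
}

#' Calibrate empirical rank percentiles for a PSSM
#'
#' Draws `nBackground` random peptides per supported length from the
#' model's background distribution, scores and sorts them. A query
#' peptide's rank percentile is
#' `100 * #(background scores >= score) / nBackground` — the convention
#' underlying "% rank" reporting in MHC binding predictors: lower rank
#' means a stronger (rarer) score.
#'
#' @param model a [PssmModel-class].
#' @param nBackground background sample size per length (>= 1000; default
#'   100000).
#' @param seed integer seed for the background draw (recorded in the
#'   calibration).
#' @return a [RankCalibration-class].
#' @export
calibrateRanks <- function(model, nBackground = 100000L, seed = 1L) {
  nBackground <- as.integer(nBackground)
  if (nBackground < 1000L) .stopf("nBackground must be >= 1000")
  set.seed(seed)
  scores <- lapply(model@matrices, function(mat)
    sort(.backgroundScores(mat, model@background, nBackground)))
  new("RankCalibration", allele = model@allele, scores = scores,
      nBackground = nBackground, seed = as.integer(seed))
}

# rank percentile of scores s against a sorted background sample v:
# 100 * #(v >= s) / n
.rankFromScores <- function(sortedBg, s) {
  n <- length(sortedBg)
  100 * (n - findInterval(s, sortedBg, left.open = TRUE)) / n
}

# score quantile within the background sample: #(v <= s) / n
.quantileFromScores <- function(sortedBg, s) {
  findInterval(s, sortedBg) / length(sortedBg)
}
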