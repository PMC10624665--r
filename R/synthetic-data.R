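#' Define a synthetic MHC allele by its anchor motif
#'
#' A synthetic allele is a set of anchor positions, each with a preferred
#' residue drawn at the given concentration (the remaining probability mass
#' is spread over the background). Negative positions count from the
#' C-terminus (`-1` = last residue), so a motif transfers across peptide
#' lengths the way real class I motifs do. The default layout uses the
#' canonical primary anchors (position 2 and the C-terminus) plus one
#' auxiliary anchor at position 3; see the methods vignette for why an
#' auxiliary anchor is part of the default motif strength.
#'
#' @param name canonical allele name (normalized).
#' @param anchorResidues character vector of preferred residues, parallel
#'   to `anchorPositions`.
#' @param anchorPositions integer vector; positive = from N-terminus,
#'   negative = from C-terminus.
#' @param concentration probability of drawing the preferred residue at an
#'   anchor position, in (0, 1].
#' @return a list describing the allele, for use in [syntheticConfig()].
#' @export
syntheticAllele <- function(name, anchorResidues,
                            anchorPositions = c(2L, 3L, -1L),
                            concentration = 0.9) {
  stopifnot(length(anchorResidues) == length(anchorPositions),
            all(anchorResidues %in% AA20),
            concentration > 0, concentration <= 1,
            all(anchorPositions != 0L))
  list(name = normalizeAllele(name),
       anchorPositions = as.integer(anchorPositions),
       anchorResidues = as.character(anchorResidues),
       concentration = concentration)
}

.defaultAlleles <- function(concentration = 0.9) {
  list(syntheticAllele("A02:01", c("L", "M", "V"),
                       concentration = concentration),
       syntheticAllele("B07:02", c("P", "R", "F"),
                       concentration = concentration))
}

#' Configuration of the synthetic immunopeptidome generator
#'
#' Bundles every parameter of the synthetic study design. The defaults
#' emulate the statistical structure a class I ligandome QC pipeline
#' assumes: ~2000 unique peptides per run, a length distribution peaked at
#' 9 residues (9mers are half of the 8-13 window), 17% random "noise"
#' peptides (so ~83% of peptides carry an allele motif), and a two-allele
#' haplotype with disjoint anchor motifs. Noise peptides draw their
#' lengths from a flat 8-13 distribution, reflecting that non-ligand
#' contaminants do not share the 9mer peak.
#'
#' @param seed integer master seed.
#' @param nProteins number of synthetic proteins.
#' @param proteinLengthRange integer range of protein lengths (residues).
#' @param alleles list of [syntheticAllele()] definitions.
#' @param mixingProportions per-allele proportions of motif peptides;
#'   together with `noiseFraction` they must sum to 1.
#' @param noiseFraction fraction of fully random peptides.
#' @param lengthProbs named probabilities over lengths 8..13 for motif
#'   peptides.
#' @param noiseLengthProbs length distribution of noise peptides (default
#'   uniform over 8..13).
#' @param nPeptides peptides drawn per run (before deduplication).
#' @param background residue background frequencies (default uniform).
#' @param embedInProteome when TRUE, peptides are verbatim windows of the
#'   generated proteome (for scan-completeness testing); anchor motifs are
#'   then not imposed on the sequence.
#' @return a list of class `ipqc_synth_config`.
#' @export
syntheticConfig <- function(seed = 1L,
                            nProteins = 500L,
                            proteinLengthRange = c(200L, 600L),
                            alleles = .defaultAlleles(),
                            mixingProportions = NULL,
                            noiseFraction = 0.17,
                            lengthProbs = c(`8` = 0.12, `9` = 0.50,
                                            `10` = 0.14, `11` = 0.10,
                                            `12` = 0.08, `13` = 0.06),
                            noiseLengthProbs = stats::setNames(rep(1 / 6, 6), 8:13),
                            nPeptides = 2000L,
                            background = uniformBackground(),
                            embedInProteome = FALSE) {
  if (is.null(mixingProportions))
    mixingProportions <- rep((1 - noiseFraction) / length(alleles),
                             length(alleles))
  stopifnot(length(mixingProportions) == length(alleles))
  if (abs(sum(mixingProportions) + noiseFraction - 1) > 1e-9)
    .stopf("mixing proportions plus noise fraction must sum to 1")
  background <- .checkBackground(background)
  maxBg <- max(background)
  for (al in alleles)
    if (al$concentration <= maxBg)
      .stopf("anchor concentration (%g) must exceed the background frequency (%g)",
             al$concentration, maxBg)
  stopifnot(identical(names(lengthProbs), as.character(8:13)),
            abs(sum(lengthProbs) - 1) < 1e-9,
            abs(sum(noiseLengthProbs) - 1) < 1e-9)
  structure(list(seed = as.integer(seed), nProteins = as.integer(nProteins),
                 proteinLengthRange = as.integer(proteinLengthRange),
                 alleles = alleles,
                 mixingProportions = mixingProportions,
                 noiseFraction = noiseFraction,
                 lengthProbs = lengthProbs,
                 noiseLengthProbs = noiseLengthProbs,
                 nPeptides = as.integer(nPeptides),
                 background = background,
                 embedInProteome = embedInProteome),
            class = "ipqc_synth_config")
}

#' Generate a synthetic proteome
#'
#' Proteins are i.i.d. residue strings from the configured background,
#' with lengths uniform over the configured range; fully reproducible from
#' the config seed.
#'
#' @param config a [syntheticConfig()].
#' @param fastaPath optional path to also write the proteome as FASTA.
#' @return named [Biostrings::AAStringSet] (accessions `SYNP0001`, ...).
#' @export
generateProteome <- function(config, fastaPath = NULL) {
  stopifnot(inherits(config, "ipqc_synth_config"))
  if (config$nProteins < 1L) .stopf("nProteins must be >= 1")
  set.seed(config$seed)
  lenRange <- seq(config$proteinLengthRange[1L], config$proteinLengthRange[2L])
  lens <- if (length(lenRange) == 1L) rep(lenRange, config$nProteins)
          else sample(lenRange, config$nProteins, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(AA20, L, replace = TRUE, prob = config$background),
          collapse = ""), character(1))
  db <- Biostrings::AAStringSet(seqs)
  names(db) <- sprintf("SYNP%04d", seq_len(config$nProteins))
  if (!is.null(fastaPath)) Biostrings::writeXStringSet(db, fastaPath)
  db
}

# draw n motif peptides of length L for one synthetic allele
.drawMotifPeptides <- function(allele, L, n, background) {
  mat <- matrix(sample(AA20, n * L, replace = TRUE, prob = background),
                nrow = n)
  for (k in seq_along(allele$anchorPositions)) {
    p <- allele$anchorPositions[k]
    pos <- if (p > 0L) p else L + 1L + p
    if (pos < 1L || pos > L) next
    hit <- stats::runif(n) < allele$concentration
    mat[hit, pos] <- allele$anchorResidues[k]
  }
  apply(mat, 1L, paste, collapse = "")
}

#' Generate a synthetic immunopeptidome run with ground truth
#'
#' Draws `nPeptides` peptides: each is either a motif peptide of one of
#' the configured alleles (anchor residues at the configured
#' concentration, background elsewhere; length from `lengthProbs`) or a
#' fully random noise peptide (length from `noiseLengthProbs`). Each
#' peptide is attributed to a uniformly drawn source protein; with
#' `embedInProteome = TRUE` the peptide *is* a verbatim window of its
#' source protein instead. Intensities are log-normal. The emitted ground
#' truth (generating allele, noise flag) is sufficient to compute every
#' downstream recovery metric without re-inference.
#'
#' @param config a [syntheticConfig()].
#' @param proteome proteome from [generateProteome()].
#' @param sampleId,replicateId,tissueLabel run labels.
#' @param seed seed for this run (default: the config seed; use different
#'   seeds for replicates).
#' @return list with `run` (a [SampleRun-class], haplotype = configured
#'   alleles) and `truth` (data.frame per unique sequence: `sequence`,
#'   `allele` (`NA` for noise), `isNoise`).
#' @export
generateRun <- function(config, proteome, sampleId = "SYN", replicateId = "r1",
                        tissueLabel = "cell_line", seed = config$seed) {
  stopifnot(inherits(config, "ipqc_synth_config"))
  set.seed(seed)
  n <- config$nPeptides
  alleleNames <- vapply(config$alleles, `[[`, character(1), "name")
  component <- sample(c(alleleNames, ".noise"), n, replace = TRUE,
                      prob = c(config$mixingProportions, config$noiseFraction))
  lens <- integer(n)
  isNoise <- component == ".noise"
  lens[!isNoise] <- sample(8:13, sum(!isNoise), replace = TRUE,
                           prob = config$lengthProbs)
  lens[isNoise] <- sample(8:13, sum(isNoise), replace = TRUE,
                          prob = config$noiseLengthProbs)
  seqs <- character(n)
  sources <- sample(names(proteome), n, replace = TRUE)
  if (config$embedInProteome) {
    pl <- Biostrings::width(proteome)[match(sources, names(proteome))]
    start <- vapply(pl - lens, function(s) sample.int(s + 1L, 1L), integer(1))
    seqs <- substr(as.character(proteome[sources]), start, start + lens - 1L)
  } else {
    for (al in config$alleles) {
      for (L in unique(lens[component == al$name])) {
        sel <- which(component == al$name & lens == L)
        seqs[sel] <- .drawMotifPeptides(al, L, length(sel), config$background)
      }
    }
    for (L in unique(lens[isNoise])) {
      sel <- which(isNoise & lens == L)
      seqs[sel] <- vapply(sel, function(i)
        paste(sample(AA20, L, replace = TRUE, prob = config$background),
              collapse = ""), character(1))
    }
  }
  intensity <- stats::rlnorm(n, meanlog = 15, sdlog = 1)
  run <- SampleRun(seqs, proteins = as.list(sources), intensity = intensity,
                   sampleId = sampleId, replicateId = replicateId,
                   haplotype = alleleNames, tissueLabel = tissueLabel)
  first <- !duplicated(seqs)
  truth <- data.frame(sequence = seqs[first],
                      allele = ifelse(isNoise[first], NA_character_,
                                      component[first]),
                      isNoise = isNoise[first], stringsAsFactors = FALSE)
  truth <- truth[match(peptideSequences(run), truth$sequence), ]
  rownames(truth) <- NULL
  list(run = run, truth = truth)
}

#' Inject a proteolytic contaminant ladder into a run
#'
#' Adds `nFragments` windows of one protein starting at consecutive
#' offsets (the "ladder profile" signature of proteolytic contamination).
#' Duplicates with existing peptides merge under the usual rules. The
#' injected protein's coverage ratio gains
#' `nFragments * fragmentLength / L(P)` from the ladder alone.
#'
#' @param run a [SampleRun-class].
#' @param proteins protein database containing `accession`.
#' @param accession protein to fragment.
#' @param nFragments number of ladder peptides (default 20).
#' @param fragmentLength ladder peptide length (default 9).
#' @return list with `run` (new [SampleRun-class]) and `ladderPeptides`
#'   (the injected sequences).
#' @export
injectContaminantLadder <- function(run, proteins, accession,
                                    nFragments = 20L, fragmentLength = 9L) {
  if (!accession %in% names(proteins))
    .stopf("accession %s not in protein database", accession)
  s <- as.character(proteins[[accession]])
  L <- nchar(s)
  if (L < nFragments + fragmentLength - 1L)
    .stopf("protein %s (length %d) too short for %d fragments of length %d",
           accession, L, nFragments, fragmentLength)
  starts <- seq_len(nFragments)
  frags <- substring(s, starts, starts + fragmentLength - 1L)
  pep <- peptideTable(run)
  medInt <- stats::median(pep$intensity, na.rm = TRUE)
  newRun <- SampleRun(c(pep$sequence, frags),
                      proteins = c(as.list(pep$proteins),
                                   rep(list(accession), length(frags))),
                      intensity = c(pep$intensity,
                                    rep(medInt, length(frags))),
                      sampleId = sampleId(run), replicateId = replicateId(run),
                      haplotype = haplotype(run),
                      tissueLabel = tissueLabel(run))
  list(run = newRun, ladderPeptides = frags)
}

#' Generate a gene-expression (log fold change) table with ground truth
#'
#' A configurable fraction of genes is labeled upregulated and draws its
#' log fold change from `logfcUp`; the rest draw from `logfcDown`. The
#' two ranges must sit on opposite sides of the selection threshold of 2,
#' so the pass set equals the upregulated label set by construction.
#'
#' @param genes character vector of gene ids.
#' @param fractionUpregulated fraction labeled upregulated.
#' @param logfcUp,logfcDown numeric ranges (min, max) for the two groups.
#' @param seed integer seed.
#' @return list with `logFC` (named numeric) and `upregulated` (character
#'   vector of gene ids).
#' @export
generateExpressionTable <- function(genes, fractionUpregulated = 0.3,
                                    logfcUp = c(3, 5), logfcDown = c(0, 1),
                                    seed = 1L) {
  stopifnot(length(genes) >= 1L)
  if (!(min(logfcUp) > 2 && max(logfcDown) <= 2))
    .stopf("logfcUp must lie above 2 and logfcDown at or below 2")
  set.seed(seed)
  nUp <- round(fractionUpregulated * length(genes))
  up <- sample(genes, nUp)
  logFC <- stats::setNames(stats::runif(length(genes), logfcDown[1L],
                                        logfcDown[2L]), genes)
  logFC[up] <- stats::runif(nUp, logfcUp[1L], logfcUp[2L])
  list(logFC = logFC, upregulated = sort(up))
}

#' Train the built-in predictor on a synthetic allele configuration
#'
#' For each configured allele, draws `nTrain` motif peptides per length,
#' builds the per-length PSSMs and calibrates rank percentiles. This is
#' the standard way to obtain a predictor matched to a synthetic study
#' design.
#'
#' @param config a [syntheticConfig()].
#' @param lengths peptide lengths to support (default 8:13).
#' @param nTrain training binders per allele and length (default 200).
#' @param nBackground calibration sample size per length (default 100000).
#' @param seed integer seed (training and calibration).
#' @return a [PssmPredictor-class].
#' @export
trainSyntheticPredictor <- function(config, lengths = 8:13, nTrain = 200L,
                                    nBackground = 100000L,
                                    seed = config$seed) {
  stopifnot(inherits(config, "ipqc_synth_config"))
  set.seed(seed)
  models <- lapply(config$alleles, function(al) {
    perLen <- lapply(lengths, function(L) {
      binders <- .drawMotifPeptides(al, L, nTrain, config$background)
      buildPssm(binders, pseudocount = 1, background = config$background,
                allele = al$name)
    })
    mergePssm(perLen)
  })
  pssmPredictor(models, nBackground = nBackground, seed = seed)
}

#' Generate a planted candidate-selection cohort
#'
#' Builds runs, predictions, expression values and gene mappings where
#' `nTrue` peptides satisfy all default selection criteria (affinity
#' below 50 nM, log fold change above 2, found in at least 3 of 4 runs,
#' 9mers) and distractor peptides each violate exactly one criterion:
#' low fold change, high affinity, too few replicates, or no gene
#' mapping. Ground truth is returned for recovery checks.
#'
#' @param seed integer seed.
#' @param nTrue number of planted true candidates (default 15).
#' @param nPerDistractor distractors per violated criterion (default 5).
#' @return list with `runs` (4 [SampleRun-class]), `predictions` (best
#'   table), `expression`, `peptideGeneMap`, `truth` (character vector of
#'   the planted candidate sequences).
#' @export
generateCandidateCohort <- function(seed = 1L, nTrue = 15L,
                                    nPerDistractor = 5L) {
  set.seed(seed)
  drawPep <- function(n, L = 9L) {
    unique(vapply(seq_len(n), function(i)
      paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1)))
  }
  # draw extra and trim so accidental duplicates cannot shrink the groups
  pool <- drawPep(4L * (nTrue + 4L * nPerDistractor))
  need <- nTrue + 4L * nPerDistractor
  stopifnot(length(pool) >= need)
  pool <- pool[seq_len(need)]
  true <- pool[seq_len(nTrue)]
  grp <- split(pool[-seq_len(nTrue)],
               rep(c("lowFC", "highAff", "fewRep", "noGene"),
                   each = nPerDistractor))
  all <- pool
  nAll <- length(all)

  inRuns <- stats::setNames(sample(3:4, nAll, replace = TRUE), all)
  inRuns[grp$fewRep] <- sample(1:2, nPerDistractor, replace = TRUE)
  runs <- lapply(1:4, function(r) {
    member <- vapply(all, function(p) {
      # peptide appears in the first inRuns[p] runs (deterministic layout)
      r <= inRuns[p]
    }, logical(1))
    SampleRun(all[member], intensity = stats::rlnorm(sum(member), 15, 1),
              sampleId = "SYN", replicateId = paste0("r", r),
              haplotype = c("A02:01", "B07:02"), tissueLabel = "tumor")
  })

  affinity <- stats::setNames(stats::runif(nAll, 5, 45), all)
  affinity[grp$highAff] <- stats::runif(nPerDistractor, 60, 500)
  predictions <- data.frame(
    peptide = all,
    allele = sample(c("A02:01", "B07:02"), nAll, replace = TRUE),
    rank = stats::runif(nAll, 0.05, 0.45),
    affinityNM = unname(affinity),
    stringsAsFactors = FALSE)
  predictions$class <- binderClass(predictions$rank)

  mapped <- setdiff(all, grp$noGene)
  geneOf <- stats::setNames(paste0("GENE", seq_along(mapped)), mapped)
  expr <- stats::setNames(stats::runif(length(mapped), 3, 5), geneOf)
  lowGenes <- geneOf[grp$lowFC]
  expr[lowGenes] <- stats::runif(length(lowGenes), 0, 1.5)
  peptideGeneMap <- data.frame(peptide = mapped, gene = unname(geneOf),
                               stringsAsFactors = FALSE)
  list(runs = runs, predictions = predictions, expression = expr,
       peptideGeneMap = peptideGeneMap, truth = sort(true))
}
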