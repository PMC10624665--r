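# Shared fixtures, built in code. Small sizes keep the default test run
# fast; the acceptance tests use the sizes stated there.

# random peptides from a background distribution
randomPeptides <- function(n, len = 9L, bg = uniformBackground()) {
  vapply(seq_len(n), function(i)
    paste(sample(AA20, len, replace = TRUE, prob = bg), collapse = ""),
    character(1))
}

# compact two-allele study design used across test files
smallConfig <- function(seed = 42L, nPeptides = 400L, nProteins = 60L,
                        proteinLengthRange = c(150L, 400L), ...) {
  syntheticConfig(seed = seed, nPeptides = nPeptides, nProteins = nProteins,
                  proteinLengthRange = proteinLengthRange, ...)
}

smallPredictor <- function(cfg = smallConfig(), nBackground = 2000L,
                           lengths = 8:13) {
  trainSyntheticPredictor(cfg, lengths = lengths, nTrain = 150L,
                          nBackground = nBackground, seed = cfg$seed)
}

# a SampleRun from bare sequences, with optional per-peptide sources
quickRun <- function(sequences, proteins = NULL, sample = "s1", rep = "r1",
                     haplotype = character(), tissue = "cell_line",
                     intensity = rep(NA_real_, length(sequences))) {
  SampleRun(sequences, proteins = proteins, intensity = intensity,
            sampleId = sample, replicateId = rep, haplotype = haplotype,
            tissueLabel = tissue)
}

# naive reference implementation of the protein coverage ratio: a plain
# per-protein loop over the run's peptides (the independent oracle)
naiveCoverageRatio <- function(run, proteins) {
  pep <- peptideTable(run)
  plist <- as.list(pep$proteins)
  accs <- sort(unique(unlist(plist, use.names = FALSE)))
  accs <- accs[accs %in% names(proteins)]
  out <- data.frame(accession = character(), ratio = numeric(),
                    stringsAsFactors = FALSE)
  for (acc in accs) {
    total <- 0L
    npep <- 0L
    for (i in seq_along(plist)) {
      if (acc %in% plist[[i]]) {
        total <- total + nchar(pep$sequence[i])
        npep <- npep + 1L
      }
    }
    L <- Biostrings::width(proteins)[match(acc, names(proteins))]
    out <- rbind(out, data.frame(accession = acc, nPeptides = npep,
                                 sumPeptideLengths = total,
                                 ratio = total / L,
                                 stringsAsFactors = FALSE))
  }
  out
}
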