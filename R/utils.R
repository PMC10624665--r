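# Internal helpers shared across modules.

#' The 20 canonical amino acids
#'
#' Alphabetical single-letter code; the column order of every PSSM and
#' residue frequency matrix in the package.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.canonicalRegex <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

.isCanonicalSeq <- function(x) {
  grepl(.canonicalRegex, x)
}

# residue-index matrix: one column per peptide, rows = positions
.peptideIndexMatrix <- function(peptides, len) {
  idx <- match(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
               AA20)
  matrix(idx, nrow = len)
}

.runLabel <- function(run) {
  paste(sampleId(run), replicateId(run), sep = ":")
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
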