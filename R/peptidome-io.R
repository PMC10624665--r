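#' Read a search-engine peptide export into SampleRun objects
#'
#' Parses a TSV/CSV peptide identification table (e.g. a PEAKS-style export)
#' and normalizes it into the package's data model. Modification annotations
#' in parentheses (e.g. `"M(+15.99)"`) are stripped, lowercase flanking
#' annotations removed, sequences uppercased, and duplicate sequences within
#' a run collapsed (intensity by maximum, source accessions by union).
#' Records whose sequence still contains a non-canonical residue after
#' normalization are rejected with a warning; the number rejected is
#' attached as attribute `"nRejected"`.
#'
#' @param path path to the table. Files ending in `.csv` are read as
#'   comma-separated, anything else as tab-separated.
#' @param dialect `"generic_tsv"` (columns `peptide`, `protein`, `sample`,
#'   `replicate`, optional `intensity`) or `"peaks_export"` (columns
#'   `Peptide`, `Accession`, `Sample`, `Replicate`, optional `Area`).
#' @param columnMap optional named character vector/list overriding the
#'   dialect's column names; names are the logical fields
#'   `peptide`, `protein`, `sample`, `replicate`, `intensity`.
#' @param haplotypes optional named list (sample id -> allele vector), e.g.
#'   from [readHaplotypes()], attached to each run.
#' @param tissueLabels optional named character vector (sample id -> tissue).
#' @return list of [SampleRun-class] objects, one per (sample, replicate)
#'   pair, named `"sample:replicate"`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("peptide\tprotein\tsample\treplicate\tintensity",
#'              "SIINFEKL\tP12345\ts1\tr1\t10"), tf)
#' runs <- readPeptideTable(tf)
#' peptideSequences(runs[[1]])
#' @export
readPeptideTable <- function(path,
                             dialect = c("generic_tsv", "peaks_export"),
                             columnMap = NULL,
                             haplotypes = NULL,
                             tissueLabels = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", check.names = FALSE)
  cmap <- switch(dialect,
    generic_tsv = c(peptide = "peptide", protein = "protein",
                    sample = "sample", replicate = "replicate",
                    intensity = "intensity"),
    peaks_export = c(peptide = "Peptide", protein = "Accession",
                     sample = "Sample", replicate = "Replicate",
                     intensity = "Area"))
  if (!is.null(columnMap)) {
    columnMap <- unlist(columnMap)
    cmap[names(columnMap)] <- columnMap
  }
  for (field in c("peptide", "protein", "sample", "replicate")) {
    if (!cmap[[field]] %in% colnames(tab))
      .stopf("required column '%s' (field '%s') missing from %s",
             cmap[[field]], field, path)
  }
  raw <- trimws(as.character(tab[[cmap[["peptide"]]]]))
  seqs <- normalizePeptideSequence(raw)
  ok <- .isCanonicalSeq(seqs)
  if (any(!ok))
    .warnf("%d record(s) rejected: non-canonical residues after stripping (e.g. %s)",
           sum(!ok), raw[!ok][1L])
  prot <- strsplit(as.character(tab[[cmap[["protein"]]]]), "\\s*;\\s*")
  intensity <- if (cmap[["intensity"]] %in% colnames(tab))
    as.numeric(tab[[cmap[["intensity"]]]]) else rep(NA_real_, nrow(tab))
  samp <- as.character(tab[[cmap[["sample"]]]])
  repl <- as.character(tab[[cmap[["replicate"]]]])

  keep <- which(ok)
  key <- paste(samp, repl, sep = ":")
  runs <- lapply(split(keep, key[keep]), function(i) {
    sid <- samp[i[1L]]
    SampleRun(seqs[i], proteins = prot[i], intensity = intensity[i],
              sampleId = sid, replicateId = repl[i[1L]],
              haplotype = if (!is.null(haplotypes) && sid %in% names(haplotypes))
                haplotypes[[sid]] else character(),
              tissueLabel = if (!is.null(tissueLabels) && sid %in% names(tissueLabels))
                tissueLabels[[sid]] else "cell_line")
  })
  attr(runs, "nRejected") <- sum(!ok)
  runs
}

#' Normalize a raw peptide string from a search-engine export
#'
#' Removes any parenthesized substring (PTM annotations such as
#' `"(+15.99)"`), strips leading/trailing lowercase flanking annotations
#' (and separating dots), and uppercases the remainder. Validation against
#' the canonical alphabet is left to the caller.
#'
#' @param x character vector of raw peptide strings.
#' @return character vector of normalized sequences.
#' @examples
#' normalizePeptideSequence("AM(+15.99)FQDK")  # "AMFQDK"
#' @export
normalizePeptideSequence <- function(x) {
  x <- gsub("\\([^()]*\\)", "", x)
  x <- sub("^[a-z.]+", "", x)
  x <- sub("[a-z.]+$", "", x)
  toupper(x)
}

#' Write SampleRun objects back to a normalized TSV
#'
#' Columns: `peptide`, `protein` (`;`-separated accessions), `intensity`,
#' `sample`, `replicate`. Reading the file back with [readPeptideTable()]
#' preserves the set of (sequence, sample, replicate) triples.
#'
#' @param runs list of [SampleRun-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePeptideTable <- function(runs, path) {
  rows <- lapply(runs, function(run) {
    pep <- peptideTable(run)
    data.frame(peptide = pep$sequence,
               protein = vapply(as.list(pep$proteins), paste,
                                character(1), collapse = ";"),
               intensity = pep$intensity,
               sample = sampleId(run),
               replicate = replicateId(run),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein database from FASTA
#'
#' Returns a named [Biostrings::AAStringSet] (the package's protein
#' database representation): names are accessions (for UniProt
#' `sp|ACC|NAME` headers, the middle field; otherwise the header token up
#' to the first whitespace), sequences are uppercased and must be over the
#' canonical 20-letter alphabet.
#'
#' @param path FASTA file.
#' @return [Biostrings::AAStringSet] with unique accession names.
#' @export
readProteinDb <- function(path) {
  db <- Biostrings::readAAStringSet(path)
  if (length(db) == 0L) .stopf("empty protein database: %s", path)
  acc <- sub("\\s.*$", "", names(db))
  uni <- grepl("^(sp|tr)\\|", acc)
  acc[uni] <- vapply(strsplit(acc[uni], "|", fixed = TRUE), `[[`, character(1), 2L)
  if (anyDuplicated(acc))
    .stopf("duplicate accession(s) in %s: %s", path,
           paste(unique(acc[duplicated(acc)]), collapse = ", "))
  seqs <- toupper(as.character(db))
  bad <- !.isCanonicalSeq(seqs)
  if (any(bad))
    .stopf("non-canonical residues in protein(s): %s",
           paste(acc[bad], collapse = ", "))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- acc
  out
}

#' Read a per-sample haplotype table
#'
#' Two tab-separated columns: sample id and a comma-separated allele list.
#' Allele names are normalized with [normalizeAllele()].
#'
#' @param path TSV file (no header).
#' @return named list: sample id -> character vector of canonical alleles.
#' @export
readHaplotypes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("sample", "alleles"))
  out <- lapply(strsplit(tab$alleles, "\\s*,\\s*"), normalizeAllele)
  names(out) <- tab$sample
  out
}

#' Read a plain-text reference peptide list
#'
#' One peptide per line (IEDB-export style after extracting the sequence
#' column); blank lines dropped, sequences uppercased.
#'
#' @param path text file.
#' @return character vector of peptides.
#' @export
readPeptideList <- function(path) {
  x <- toupper(trimws(readLines(path)))
  x[nzchar(x)]
}

#' Write a JSON manifest describing a set of runs
#'
#' @param runs list of [SampleRun-class] objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(runs, path) {
  manifest <- lapply(unname(runs), function(run) {
    list(sample = sampleId(run), replicate = replicateId(run),
         tissue = tissueLabel(run), n_peptides = nPeptides(run),
         haplotype = as.list(haplotype(run)))
  })
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
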