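#' Accessors for ipQC classes
#'
#' Small accessor generics: prefer these over direct slot access.
#'
#' @param x an ipQC object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("replicateId", function(x) standardGeneric("replicateId"))
#' @rdname accessors
#' @export
setGeneric("tissueLabel", function(x) standardGeneric("tissueLabel"))
#' @rdname accessors
#' @export
setGeneric("haplotype", function(x) standardGeneric("haplotype"))
#' @rdname accessors
#' @export
setGeneric("peptideTable", function(x) standardGeneric("peptideTable"))
#' @rdname accessors
#' @export
setGeneric("peptideSequences", function(x) standardGeneric("peptideSequences"))
#' @rdname accessors
#' @export
setGeneric("nPeptides", function(x) standardGeneric("nPeptides"))
#' @rdname accessors
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))
#' @rdname accessors
#' @export
setGeneric("supportedLengths", function(x) standardGeneric("supportedLengths"))
#' @rdname accessors
#' @export
setGeneric("coverageCutoff", function(x) standardGeneric("coverageCutoff"))

#' @rdname accessors
#' @param capped logical; return the display copy with values above the cap
#'   truncated (diagonal included), or the raw percentages.
#' @export
setGeneric("overlapValues",
           function(x, capped = FALSE) standardGeneric("overlapValues"))

setMethod("sampleId", "SampleRun", function(x) x@sampleId)
setMethod("replicateId", "SampleRun", function(x) x@replicateId)
setMethod("tissueLabel", "SampleRun", function(x) x@tissueLabel)
setMethod("haplotype", "SampleRun", function(x) x@haplotype)
setMethod("peptideTable", "SampleRun", function(x) x@peptides)
setMethod("peptideSequences", "SampleRun", function(x) x@peptides$sequence)
setMethod("nPeptides", "SampleRun", function(x) nrow(x@peptides))

setMethod("alleles", "PssmModel", function(x) x@allele)
setMethod("alleles", "PssmPredictor", function(x) names(x@models))
setMethod("supportedLengths", "PssmModel",
          function(x) sort(as.integer(names(x@matrices))))
setMethod("supportedLengths", "PssmPredictor", function(x) {
  sort(unique(unlist(lapply(x@models, supportedLengths), use.names = FALSE)))
})

setMethod("coverageCutoff", "CutoffCalibration", function(x) x@cutoff)

setMethod("overlapValues", "OverlapMatrix", function(x, capped = FALSE) {
  v <- x@values
  if (capped) v[v > x@cap] <- x@cap
  v
})

setMethod("show", "SampleRun", function(object) {
  cat(sprintf("SampleRun %s:%s (%s)\n", object@sampleId, object@replicateId,
              object@tissueLabel))
  cat(sprintf("  %d unique peptides; haplotype: %s\n", nrow(object@peptides),
              if (length(object@haplotype))
                paste(object@haplotype, collapse = ", ") else "<none>"))
})

setMethod("show", "PssmModel", function(object) {
  cat(sprintf("PssmModel for %s; lengths %s; pseudocount %g\n",
              object@allele,
              paste(supportedLengths(object), collapse = ","),
              object@pseudocount))
})

setMethod("show", "PssmPredictor", function(object) {
  cat(sprintf("PssmPredictor: %d allele(s) [%s]; lengths %s\n",
              length(object@models),
              paste(names(object@models), collapse = ", "),
              paste(supportedLengths(object), collapse = ",")))
  if (length(object@calibrations))
    cat(sprintf("  calibration: n = %d background peptides per length\n",
                object@calibrations[[1L]]@nBackground))
})

setMethod("show", "OverlapMatrix", function(object) {
  cat(sprintf("OverlapMatrix (%s, cap %g%%) over %d samples\n",
              object@mode, object@cap, length(object@samples)))
})

setMethod("show", "CutoffCalibration", function(object) {
  cat(sprintf("CutoffCalibration: cutoff %.4g (mean of %d run 95th percentiles)\n",
              object@cutoff, length(object@runIds)))
})

setMethod("show", "CandidateCriteria", function(object) {
  cat(sprintf(paste0("CandidateCriteria: affinity < %g nM, logFC > %g, ",
                     ">= %d replicates, prefer %dmers, top %d\n"),
              object@affinityMaxNM, object@minLogFC, object@minReplicates,
              object@preferredLength, object@topK))
})
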