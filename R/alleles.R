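#' Normalize MHC allele names to a canonical form
#'
#' Accepts the common dialects of class I allele names and returns the
#' canonical short form used throughout the package: human four-digit names
#' become `"A02:01"` (locus letter + two-digit group + ":" + two-digit
#' protein; `HLA-` prefix and `*` separator dropped), murine names become
#' `"H2-Kd"` style. The function is idempotent on its own output.
#'
#' @param name character vector of allele names, e.g. `"HLA-A*02:01"`,
#'   `"HLA-A02:01"`, `"A*02:01"`, `"A02:01"`, `"H2-Kd"`, `"H-2Kd"`.
#' @return character vector of canonical names.
#' @examples
#' normalizeAllele(c("HLA-A*02:01", "A02:01", "H-2Kd"))
#' @export
normalizeAllele <- function(name) {
  name <- trimws(as.character(name))
  out <- character(length(name))
  # human class I: optional HLA- prefix, locus letter, optional *, 2-3 digit
  # group, optional :, 2-3 digit protein
  human <- "^(?:HLA-)?([A-Z])\\*?([0-9]{2,3}):?([0-9]{2,3})$"
  # murine: H2 / H-2, optional dash, locus letter, lowercase haplotype letter
  mouse <- "^[Hh]-?2-?([A-Z])([a-z])$"
  isH <- grepl(human, name)
  isM <- !isH & grepl(mouse, name)
  bad <- !(isH | isM)
  if (any(bad))
    .stopf("unparseable allele name(s): %s",
           paste(unique(name[bad]), collapse = ", "))
  out[isH] <- sub(human, "\\1\\2:\\3", name[isH])
  out[isM] <- sub(mouse, "H2-\\1\\2", name[isM])
  out
}

.isHumanAllele <- function(name) {
  grepl("^[A-Z][0-9]{2,3}:[0-9]{2,3}$", name)
}

# two-digit serological group, e.g. "A02:01" -> "A02"; murine names unchanged
.alleleGroup <- function(name) {
  ifelse(.isHumanAllele(name), sub(":.*$", "", name), name)
}
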