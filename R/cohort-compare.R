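.peptideSets <- function(x) {
  if (is(x, "SampleRun")) return(stats::setNames(list(peptideSequences(x)),
                                                 .runLabel(x)))
  stopifnot(is.list(x))
  sets <- lapply(x, function(el)
    if (is(el, "SampleRun")) peptideSequences(el) else as.character(el))
  nm <- names(x)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- vapply(seq_along(x), function(i)
      if (is(x[[i]], "SampleRun")) .runLabel(x[[i]]) else paste0("set", i),
      character(1))
  stats::setNames(sets, nm)
}

#' Pairwise peptide-set overlap between samples
#'
#' Overlap percentage between every pair of peptide sets. In
#' `"smaller_set"` mode (default; Szymkiewicz-Simpson) the overlap of A and
#' B is `100 * |A n B| / min(|A|, |B|)`, which is symmetric; in
#' `"row_set"` mode it is `100 * |A n B| / |A|` per row. The cap (default
#' 40%, to keep heatmaps readable when replicates overlap heavily) only
#' affects the rendered copy: raw values are retained and used for
#' clustering.
#'
#' @param x list of [SampleRun-class] objects and/or character peptide
#'   vectors (named; >= 2 non-empty sets).
#' @param mode `"smaller_set"` or `"row_set"`.
#' @param cap display cap in percent.
#' @return an [OverlapMatrix-class].
#' @export
pairwiseOverlap <- function(x, mode = c("smaller_set", "row_set"), cap = 40) {
  mode <- match.arg(mode)
  sets <- lapply(.peptideSets(x), unique)
  if (length(sets) < 2L) .stopf("at least 2 peptide sets required")
  empty <- lengths(sets) == 0L
  if (any(empty)) .stopf("empty peptide set(s): %s",
                         paste(names(sets)[empty], collapse = ", "))
  k <- length(sets)
  v <- matrix(0, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      denom <- switch(mode,
                      smaller_set = min(length(sets[[i]]), length(sets[[j]])),
                      row_set = length(sets[[i]]))
      v[i, j] <- 100 * inter / denom
    }
  }
  new("OverlapMatrix", samples = names(sets), values = v,
      cap = cap, mode = mode)
}

# deterministic agglomerative clustering on a symmetric distance matrix.
# Ties in the minimum inter-cluster distance merge the pair of clusters
# with the lowest creation indices first (singletons in input order, then
# merged clusters in creation order).
.agglomerate <- function(D, method = c("average", "complete")) {
  method <- match.arg(method)
  n <- nrow(D)
  labels <- rownames(D)
  if (n < 2L) .stopf("at least 2 items required for clustering")
  # active cluster bookkeeping: hclust ids (-i singletons, +k merge rows)
  id <- -seq_len(n)
  size <- rep(1L, n)
  d <- D
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(id)
    best <- c(NA_integer_, NA_integer_)
    bestd <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        if (d[i, j] < bestd - 1e-12) {
          bestd <- d[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- bestd
    newd <- switch(method,
      average = (size[i] * d[i, ] + size[j] * d[j, ]) / (size[i] + size[j]),
      complete = pmax(d[i, ], d[j, ]))
    newd <- newd[-c(i, j)]
    keep <- setdiff(seq_len(m), c(i, j))
    d <- d[keep, keep, drop = FALSE]
    d <- rbind(cbind(d, newd), c(newd, 0))
    nsize <- size[i] + size[j]
    id <- c(id[keep], step)
    size <- c(size[keep], nsize)
  }
  leafOrder <- function(k) {
    if (k < 0L) return(-k)
    c(leafOrder(merge[k, 1L]), leafOrder(merge[k, 2L]))
  }
  structure(list(merge = merge, height = height,
                 order = leafOrder(n - 1L), labels = labels,
                 method = method, call = match.call(),
                 dist.method = "custom"),
            class = "hclust")
}

#' Hierarchically cluster samples by immunopeptidome overlap
#'
#' Agglomerative clustering on distance `100 - overlap%` using the raw
#' (uncapped) symmetric overlap matrix. Merge order is deterministic: ties
#' in the minimum inter-cluster distance are broken by merging the
#' lowest-index pair first.
#'
#' @param om an [OverlapMatrix-class] in `smaller_set` mode.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return an object of class `hclust` (see [stats::hclust]); convert with
#'   `ape::as.phylo()` or export with [writeNewick()].
#' @export
clusterOverlap <- function(om, linkage = c("average", "complete")) {
  stopifnot(is(om, "OverlapMatrix"))
  linkage <- match.arg(linkage)
  if (om@mode != "smaller_set")
    .stopf("clustering requires the symmetric smaller_set mode; recompute pairwiseOverlap(x, mode = \"smaller_set\")")
  D <- 100 - overlapValues(om, capped = FALSE)
  diag(D) <- 0
  .agglomerate(D, linkage)
}

#' Write a merge tree to a Newick file
#'
#' @param hc an `hclust` object, e.g. from [clusterOverlap()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' One-hot encode sample haplotypes
#'
#' Builds the binary sample x allele matrix used for haplotype clustering.
#' Four-digit human alleles are reduced to their two-digit group (e.g.
#' `A02:01 -> A02`) only when every allele aggregated under that group
#' maps to the same peptide-binding motif group in `motifGroups`; with no
#' map supplied the reduction is applied unconditionally, with a warning.
#' Alleles present in at most one sample are dropped (the shared-allele
#' rule), so every retained column has at least two ones.
#'
#' @param haps named list: sample id -> character vector of allele names
#'   (normalized internally).
#' @param motifGroups optional named character vector mapping canonical
#'   four-digit allele names to motif-group labels.
#' @return list with `matrix` (binary sample x allele), `aggregation`
#'   (data.frame `allele` -> `column`) and `dropped` (alleles removed by
#'   the shared-allele rule).
#' @export
encodeHaplotypes <- function(haps, motifGroups = NULL) {
  stopifnot(is.list(haps), !is.null(names(haps)))
  haps <- lapply(haps, normalizeAllele)
  if (!is.null(motifGroups)) names(motifGroups) <- normalizeAllele(names(motifGroups))
  all4 <- sort(unique(unlist(haps, use.names = FALSE)))
  grp <- .alleleGroup(all4)
  column <- all4
  for (g in unique(grp[.isHumanAllele(all4)])) {
    members <- all4[grp == g]
    aggregate <- if (is.null(motifGroups)) {
      TRUE
    } else {
      all(members %in% names(motifGroups)) &&
        length(unique(motifGroups[members])) == 1L
    }
    if (aggregate) column[grp == g] <- g
  }
  if (is.null(motifGroups) && any(column != all4))
    .warnf("no motif-group map supplied; four-digit alleles aggregated to two-digit groups unconditionally")
  cols <- sort(unique(column))
  mat <- matrix(0L, length(haps), length(cols),
                dimnames = list(names(haps), cols))
  for (s in names(haps)) {
    hit <- unique(column[match(haps[[s]], all4)])
    mat[s, hit] <- 1L
  }
  shared <- colSums(mat) >= 2L
  dropped <- colnames(mat)[!shared]
  list(matrix = mat[, shared, drop = FALSE],
       aggregation = data.frame(allele = all4, column = column,
                                stringsAsFactors = FALSE),
       dropped = dropped)
}

#' Cluster samples by one-hot haplotype encoding
#'
#' Hamming distance between the binary haplotype vectors, agglomerated
#' with the same deterministic procedure as [clusterOverlap()].
#'
#' @param encoding result of [encodeHaplotypes()].
#' @param linkage `"average"` or `"complete"`.
#' @return an `hclust` object.
#' @export
clusterHaplotypes <- function(encoding, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  D <- as.matrix(stats::dist(encoding$matrix, method = "manhattan"))
  .agglomerate(D, linkage)
}

#' Annotate run peptides against known-ligand reference sets
#'
#' Exact sequence matching against named reference peptide lists (e.g.
#' database exports of previously reported ligands). Reports, per set, the
#' percentage of the run's peptides of the chosen length found in the set,
#' plus per-peptide membership flags.
#'
#' @param run a [SampleRun-class].
#' @param referenceSets named list of character peptide vectors.
#' @param lengths lengths entering the percentage (default 9; `NULL` for
#'   all peptides).
#' @return list with `percent` (named numeric; `NA` for empty reference
#'   sets) and `flags` (data.frame: `peptide` plus one logical column per
#'   set, over all run peptides).
#' @export
annotateKnown <- function(run, referenceSets, lengths = 9L) {
  stopifnot(is.list(referenceSets), !is.null(names(referenceSets)))
  referenceSets <- lapply(referenceSets, function(s) unique(toupper(s)))
  seqs <- peptideSequences(run)
  inScope <- if (is.null(lengths)) rep(TRUE, length(seqs))
             else nchar(seqs) %in% lengths
  flags <- data.frame(peptide = seqs, stringsAsFactors = FALSE)
  percent <- stats::setNames(numeric(length(referenceSets)),
                             names(referenceSets))
  for (nm in names(referenceSets)) {
    hit <- seqs %in% referenceSets[[nm]]
    flags[[nm]] <- hit
    percent[nm] <- if (!length(referenceSets[[nm]]) || !any(inScope))
      NA_real_ else 100 * mean(hit[inScope])
  }
  list(percent = percent, flags = flags)
}
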