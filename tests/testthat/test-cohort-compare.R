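test_that("pairwise overlap percentages match set arithmetic", {
  sets <- list(A = c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD"),
               B = c("CCCCCCCCC", "DDDDDDDDD", "EEEEEEEEE"))
  om <- pairwiseOverlap(sets)
  v <- overlapValues(om)
  expect_equal(v["A", "B"], 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(diag(v), c(A = 100, B = 100))
  # identity and disjoint extremes
  expect_equal(overlapValues(pairwiseOverlap(list(A = sets$A,
                                                  B = sets$A)))["A", "B"], 100)
  expect_equal(overlapValues(pairwiseOverlap(list(A = sets$A,
                                                  B = "FFFFFFFFF")))["A", "B"], 0)
  expect_error(pairwiseOverlap(list(A = sets$A, B = character())), "B")
})

test_that("smaller_set matrices are symmetric with unit diagonal; capping is display-only", {
  set.seed(61)
  pool <- randomPeptides(80, 9)
  sets <- lapply(1:4, function(i) sample(pool, sample(20:60, 1)))
  names(sets) <- paste0("s", 1:4)
  om <- pairwiseOverlap(sets, cap = 40)
  v <- overlapValues(om)
  expect_equal(v, t(v))
  expect_equal(unname(diag(v)), rep(100, 4))
  capped <- overlapValues(om, capped = TRUE)
  expect_true(all(capped <= 40))
  expect_equal(v[v <= 40], capped[v <= 40])  # raw values retained below cap
})

test_that("row_set mode normalizes per row and is rejected for clustering", {
  sets <- list(A = c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD"),
               B = c("CCCCCCCCC", "DDDDDDDDD"))
  om <- pairwiseOverlap(sets, mode = "row_set")
  v <- overlapValues(om)
  expect_equal(v["A", "B"], 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(v["B", "A"], 100)
  expect_error(clusterOverlap(om), "smaller_set")
})

test_that("clustering merges the planted high-overlap pair first", {
  # A and B share 8 of 10 peptides; C shares about 5% with either
  base <- randomPeptides(30, 9)
  A <- base[1:10]
  B <- c(base[1:8], base[11:12])
  C <- c(base[8], base[13:21])
  om <- pairwiseOverlap(list(A = A, B = B, C = C))
  hc <- clusterOverlap(om)
  expect_identical(sort(hc$merge[1, ]), c(-2L, -1L))  # {A, B} first
  expect_equal(hc$height[1], 100 - overlapValues(om)["A", "B"])
  # two samples: a single merge
  hc2 <- clusterOverlap(pairwiseOverlap(list(A = A, B = B)))
  expect_identical(nrow(hc2$merge), 1L)
})

test_that("equal distances merge the lowest-index pair first", {
  D <- matrix(50, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  diag(D) <- 100
  om <- new("OverlapMatrix", samples = paste0("s", 1:4), values = D,
            cap = 40, mode = "smaller_set")
  hc <- clusterOverlap(om)
  expect_identical(hc$merge[1, ], c(-2L, -1L))
})

test_that("deterministic agglomeration agrees with stats::hclust on tie-free input", {
  set.seed(63)
  for (i in 1:5) {
    n <- 6
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- runif(n * (n - 1) / 2, 10, 90)
    D <- D + t(D)
    dimnames(D) <- list(paste0("x", 1:n), paste0("x", 1:n))
    for (method in c("average", "complete")) {
      mine <- ipQC:::.agglomerate(D, method)
      ref <- stats::hclust(as.dist(D), method = method)
      expect_equal(stats::cophenetic(mine), stats::cophenetic(ref),
                   tolerance = 1e-9)
    }
  }
})

test_that("newick export round-trips through ape", {
  om <- pairwiseOverlap(list(A = randomPeptides(10, 9),
                             B = randomPeptides(10, 9),
                             C = randomPeptides(10, 9)))
  tf <- tempfile(fileext = ".nwk")
  writeNewick(clusterOverlap(om), tf)
  tree <- ape::read.tree(tf)
  expect_setequal(tree$tip.label, c("A", "B", "C"))
})

test_that("haplotype encoding applies the shared-allele and motif-group rules", {
  haps <- list(s1 = c("HLA-A*02:01", "B07:02"),
               s2 = c("A02:06", "B07:02"),
               s3 = c("C07:01"))
  sameMotif <- c("A02:01" = "A2", "A02:06" = "A2")
  enc <- encodeHaplotypes(haps, motifGroups = sameMotif)
  expect_identical(colnames(enc$matrix), c("A02", "B07:02"))
  expect_equal(unname(enc$matrix[, "A02"]), c(1L, 1L, 0L))
  # C07:01 is private to s3: dropped
  expect_true("C07:01" %in% enc$dropped)
  expect_true(all(colSums(enc$matrix) >= 2L))

  # a splitting map keeps four-digit resolution (columns then private -> dropped)
  splitMap <- c("A02:01" = "A2a", "A02:06" = "A2b")
  enc2 <- encodeHaplotypes(haps, motifGroups = splitMap)
  expect_false("A02" %in% colnames(enc2$matrix))
  expect_true(all(c("A02:01", "A02:06") %in% enc2$dropped))
  expect_identical(colnames(enc2$matrix), "B07:02")

  # no map: unconditional aggregation with a warning
  expect_warning(enc3 <- encodeHaplotypes(haps), "unconditionally")
  expect_true("A02" %in% colnames(enc3$matrix))
})

test_that("encoding never keeps a column with fewer than two ones", {
  set.seed(65)
  allAlleles <- c("A02:01", "A02:06", "B07:02", "B08:01", "C07:01", "H2-Kd")
  for (i in 1:10) {
    haps <- lapply(1:5, function(j)
      sample(allAlleles, sample(1:4, 1)))
    names(haps) <- paste0("s", 1:5)
    enc <- suppressWarnings(encodeHaplotypes(haps))
    if (ncol(enc$matrix))
      expect_true(all(colSums(enc$matrix) >= 2L))
  }
})

test_that("haplotype clustering groups identical haplotypes first", {
  haps <- list(s1 = c("A02:01", "B07:02"),
               s2 = c("A02:01", "B07:02"),
               s3 = c("C07:01", "B08:01"),
               s4 = c("C07:01", "B08:01"))
  enc <- suppressWarnings(encodeHaplotypes(haps))
  hc <- clusterHaplotypes(enc)
  expect_identical(sort(hc$merge[1, ]), c(-2L, -1L))
  expect_equal(hc$height[1], 0)
})

test_that("known-ligand annotation reports exact-match percentages", {
  run <- quickRun(randomPeptides(10, 9))
  peps <- peptideSequences(run)
  refs <- list(overall = peps, none = "WWWWWWWWW",
               some = peps[1:7], empty = character())
  ann <- annotateKnown(run, refs)
  expect_equal(unname(ann$percent["overall"]), 100)
  expect_equal(unname(ann$percent["none"]), 0)
  expect_equal(unname(ann$percent["some"]), 70)
  expect_true(is.na(ann$percent["empty"]))
  expect_identical(sum(ann$flags$some), 7L)
})
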