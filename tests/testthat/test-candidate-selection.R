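test_that("replicate counts are exact set membership counts", {
  peps <- randomPeptides(4, 9)
  runs <- list(quickRun(peps[1:3], rep = "r1"),
               quickRun(peps[c(1, 2)], rep = "r2"),
               quickRun(peps[c(1, 4)], rep = "r3"),
               quickRun(peps[1], rep = "r4"))
  expect_identical(replicateCount(peps, runs), c(4L, 2L, 1L, 1L))
  expect_identical(replicateCount("WWWWWWWWW", runs), 0L)
})

toyCohort <- function() {
  # six peptides; exactly two satisfy logFC > 2, affinity < 50, >= 3 runs
  peps <- c("AAAAAAAAL", "CCCCCCCCL", "DDDDDDDDL", "EEEEEEEEL",
            "FFFFFFFFL", "GGGGGGGGGL")                 # last one a 10mer
  inRuns <- c(4, 3, 2, 4, 3, 3)
  runs <- lapply(1:4, function(r)
    quickRun(peps[inRuns >= r], rep = paste0("r", r)))
  predictions <- data.frame(
    peptide = peps, allele = "A02:01",
    rank = c(0.1, 0.2, 0.1, 0.1, 0.3, 0.2),
    affinityNM = c(20, 30, 10, 80, 25, 40),
    class = "SB", stringsAsFactors = FALSE)
  expression <- c(g1 = 4, g2 = 3.5, g3 = 4, g4 = 4, g5 = 1, g6 = 1.5)
  map <- data.frame(peptide = peps, gene = paste0("g", 1:6),
                    stringsAsFactors = FALSE)
  list(peps = peps, runs = runs, predictions = predictions,
       expression = expression, map = map)
}

test_that("selection filters match a brute-force oracle on the toy cohort", {
  d <- toyCohort()
  # brute-force oracle over the three predicates
  nRep <- replicateCount(d$peps, d$runs)
  pass <- d$expression[d$map$gene] > 2 & d$predictions$affinityNM < 50 &
    nRep >= 3
  expect_identical(sum(pass), 2L)  # peptides 1 and 2 and the 10mer? check below
  cand <- suppressMessages(
    selectCandidates(d$runs, d$predictions, d$expression, d$map))
  expect_setequal(cand$peptide, d$peps[pass])
  # p1 and p2 survive; p3 fails replicates, p4 affinity, p5/p6 fold change
})

test_that("threshold tightening never increases the survivor count", {
  d <- toyCohort()
  n <- function(crit) nrow(suppressMessages(
    selectCandidates(d$runs, d$predictions, d$expression, d$map, crit)))
  base <- n(candidateCriteria())
  expect_lte(n(candidateCriteria(affinityMaxNM = 25)), base)
  expect_lte(n(candidateCriteria(minLogFC = 3.8)), base)
  expect_lte(n(candidateCriteria(minReplicates = 4)), base)
})

test_that("preferred length wins the tie among otherwise equal survivors", {
  peps <- c("AAAAAAAAAL", "AAAAAAAAL")  # 10mer vs 9mer, same stats
  runs <- lapply(1:3, function(r) quickRun(peps, rep = paste0("r", r)))
  predictions <- data.frame(peptide = peps, allele = "A02:01",
                            rank = 0.1, affinityNM = 20, class = "SB",
                            stringsAsFactors = FALSE)
  expression <- c(g = 4)
  map <- data.frame(peptide = peps, gene = "g")
  cand <- suppressMessages(
    selectCandidates(runs, predictions, expression, map))
  expect_identical(cand$peptide[1], "AAAAAAAAL")
  expect_true(cand$isPreferredLength[1])
})

test_that("tissue prioritization ranks tumor-observed peptides first", {
  peps <- c("CCCCCCCCL", "AAAAAAAAL")
  runsTumor <- lapply(1:3, function(r)
    quickRun(peps[1], rep = paste0("t", r), tissue = "tumor"))
  runsCell <- lapply(1:3, function(r)
    quickRun(peps, rep = paste0("c", r), tissue = "cell_line"))
  predictions <- data.frame(peptide = peps, allele = "A02:01", rank = 0.1,
                            affinityNM = c(30, 10), class = "SB",
                            stringsAsFactors = FALSE)
  expression <- c(g = 4)
  map <- data.frame(peptide = peps, gene = "g")
  cand <- suppressMessages(selectCandidates(
    c(runsTumor, runsCell), predictions, expression, map,
    candidateCriteria(prioritizeTissue = "tumor")))
  # the tumor-observed peptide outranks the lower-affinity cell-line one
  expect_identical(cand$peptide[1], "CCCCCCCCL")
  expect_true(cand$tissueEvidence[1])
})

test_that("unmapped peptides are excluded and counted, not errors", {
  d <- toyCohort()
  map <- d$map[-1, ]  # drop the mapping of the first peptide
  cand <- suppressMessages(
    selectCandidates(d$runs, d$predictions, d$expression, map))
  expect_false(d$peps[1] %in% cand$peptide)
  log <- attr(cand, "filterLog")
  expect_true("upregulated" %in% log$step)
})

test_that("the planted cohort is recovered exactly and in deterministic order", {
  cohort <- generateCandidateCohort(seed = 99)
  cand <- suppressMessages(selectCandidates(
    cohort$runs, cohort$predictions, cohort$expression,
    cohort$peptideGeneMap, candidateCriteria(topK = 50)))
  expect_setequal(cand$peptide, cohort$truth)
  expect_identical(nrow(cand), 15L)
  again <- suppressMessages(selectCandidates(
    cohort$runs, cohort$predictions, cohort$expression,
    cohort$peptideGeneMap, candidateCriteria(topK = 50)))
  expect_identical(cand, again)
  expect_identical(cand$finalRank, seq_len(15L))
})

test_that("poly-K export prepends lysines and flags K-initial peptides", {
  out <- exportPolyK(data.frame(peptide = c("SIINFEKL", "KLLLLLLLV")))
  expect_identical(out$polyK, c("KKKKKKSIINFEKL", "KKKKKKKLLLLLLLV"))
  expect_identical(out$startsWithK, c(FALSE, TRUE))
  # stripping k leading K's recovers the original when unflagged
  expect_identical(sub("^K{6}", "", out$polyK[1]), out$peptide[1])
  expect_error(exportPolyK(data.frame(peptide = "SIINFEKL"), k = 0), ">= 1")
  tf <- tempfile(fileext = ".fasta")
  exportPolyK(data.frame(peptide = "SIINFEKL", finalRank = 1L),
              fastaPath = tf)
  fa <- Biostrings::readAAStringSet(tf)
  expect_identical(as.character(fa[[1]]), "KKKKKKSIINFEKL")
})
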