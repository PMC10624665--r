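protDb <- function(lens, prefix = "P") {
  set.seed(7)
  seqs <- vapply(lens, function(L)
    paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
  db <- Biostrings::AAStringSet(seqs)
  names(db) <- paste0(prefix, seq_along(lens))
  db
}

test_that("coverage ratio equals summed peptide length over protein length", {
  db <- protDb(c(100, 50))
  run <- quickRun(c(randomPeptides(1, 9), randomPeptides(1, 9),
                    randomPeptides(1, 10)),
                  proteins = list("P1", "P1", "P1"))
  cov <- proteinCoverageRatio(run, db)
  expect_identical(cov$accession, "P1")       # P2 has no peptides: absent
  expect_identical(cov$nPeptides, 3L)
  expect_identical(cov$sumPeptideLengths, 28L)
  expect_equal(cov$ratio, 0.28)
})

test_that("a nested ladder yields the expected extreme ratio", {
  db <- protDb(60)
  run <- quickRun("AAAAAAAAA", proteins = list(character()))
  inj <- injectContaminantLadder(run, db, "P1", nFragments = 30,
                                 fragmentLength = 9)
  cov <- proteinCoverageRatio(inj$run, db)
  # 30 overlapping 9mers on a 60-residue protein: 270/60
  expect_equal(cov$ratio[cov$accession == "P1"], 4.5)
})

test_that("degenerate databases and unknown accessions are handled", {
  db <- protDb(c(100, 0))
  run <- quickRun(randomPeptides(1, 9), proteins = list("P1"))
  expect_error(proteinCoverageRatio(run, db), "zero-length")
  db2 <- protDb(100)
  run2 <- quickRun(randomPeptides(2, 9), proteins = list("P1", "MISSING"))
  expect_warning(cov <- proteinCoverageRatio(run2, db2), "not in the protein")
  expect_identical(cov$accession, "P1")
})

test_that("vectorized ratios equal the naive per-protein loop", {
  db <- protDb(sample(50:300, 15))
  set.seed(51)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    run <- quickRun(randomPeptides(n, sample(8:13, 1)),
                    proteins = replicate(n, sample(names(db),
                                                   sample(1:3, 1)),
                                         simplify = FALSE))
    fast <- proteinCoverageRatio(run, db)
    slow <- naiveCoverageRatio(run, db)
    expect_identical(fast$accession, slow$accession)
    expect_identical(fast$nPeptides, slow$nPeptides)
    expect_equal(fast$ratio, slow$ratio)
  }
})

test_that("cutoff calibration is the mean of per-run 95th percentiles", {
  # proteome constructed so the ratio multiset is {0.01 x95, 0.5 x5}:
  # 95 proteins of length 900 with one 9mer each; 5 of length 90 with five
  # distinct 9mers each
  lens <- c(rep(900, 95), rep(90, 5))
  db <- protDb(lens)
  seqs <- character(); prots <- list()
  for (i in 1:95) {
    seqs <- c(seqs, substr(as.character(db[[i]]), 1, 9))
    prots <- c(prots, list(names(db)[i]))
  }
  for (i in 96:100) {
    for (k in 0:4) {
      seqs <- c(seqs, substr(as.character(db[[i]]), 1 + 10 * k, 9 + 10 * k))
      prots <- c(prots, list(names(db)[i]))
    }
  }
  run <- quickRun(seqs, proteins = prots)
  cov <- proteinCoverageRatio(run, db)
  expect_equal(sort(unique(cov$ratio)), c(0.01, 0.5))
  # type-7 quantile oracle evaluated by hand: h = 0.95*(100-1)+1 = 95.05,
  # between the 95th (0.01) and 96th (0.5) order statistics
  expected <- 0.01 + 0.05 * (0.5 - 0.01)
  calib <- calibrateCutoff(list(run), db)
  expect_equal(coverageCutoff(calib), expected)
  # two identical runs: the mean leaves the cutoff unchanged
  run2 <- quickRun(seqs, proteins = prots, rep = "r2")
  expect_equal(coverageCutoff(calibrateCutoff(list(run, run2), db)), expected)
})

test_that("runs covering too few proteins are excluded from calibration", {
  db <- protDb(rep(200, 30))
  thin <- quickRun(randomPeptides(5, 9),
                   proteins = as.list(names(db)[1:5]))
  rich <- quickRun(randomPeptides(25, 9),
                   proteins = as.list(names(db)[1:25]), rep = "r2")
  expect_warning(calib <- calibrateCutoff(list(thin, rich), db), "excluded")
  expect_identical(calib@runIds, "s1:r2")
  expect_warning(expect_error(calibrateCutoff(list(thin), db), "cannot calibrate"))
})

test_that("flagging removes a peptide only when all its sources are flagged", {
  db <- protDb(c(60, 500))
  run <- quickRun(c("CCCCCCCCC", "DDDDDDDDD"),
                  proteins = list("P2", c("P1", "P2")))
  inj <- injectContaminantLadder(run, db, "P1", 20, 9)
  res <- flagAndClean(inj$run, db, cutoff = 0.4)
  expect_true(res$report$flagged[res$report$accession == "P1"])
  expect_false(res$report$flagged[res$report$accession == "P2"])
  # ladder-exclusive peptides gone, the shared peptide retained
  expect_setequal(res$removed, inj$ladderPeptides)
  expect_true("DDDDDDDDD" %in% peptideSequences(res$run))
  expect_true("CCCCCCCCC" %in% peptideSequences(res$run))
  expect_true(all(res$report$flagged == (res$report$ratio > 0.4)))
})

test_that("cleaning is idempotent and the identity when nothing is flagged", {
  cfg <- smallConfig(seed = 55, nPeptides = 200, nProteins = 40)
  prot <- generateProteome(cfg)
  run <- generateRun(cfg, prot, seed = 56)$run
  big <- flagAndClean(run, prot, cutoff = 100)
  expect_identical(peptideSequences(big$run), peptideSequences(run))
  expect_identical(big$removed, character(0))
  calib <- calibrateCutoff(list(run), prot)
  once <- flagAndClean(run, prot, coverageCutoff(calib))
  twice <- flagAndClean(once$run, prot, coverageCutoff(calib))
  expect_identical(peptideSequences(twice$run), peptideSequences(once$run))
  expect_error(flagAndClean(run, prot, cutoff = -1), "positive")
})
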