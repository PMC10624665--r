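test_that("length distribution arithmetic and summary fractions", {
  run <- quickRun(c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD", "EEEEEEEEEE"))
  ld <- lengthDistribution(run)
  expect_equal(ld$fraction9OfAll, 75)
  expect_equal(ld$fraction8to13, 100)
  expect_equal(ld$fraction9Of8to13, 75)
  expect_equal(sum(ld$table$percentage), 100)

  long <- quickRun(c("AAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCC"))  # two 15mers
  ld2 <- lengthDistribution(long)
  expect_equal(ld2$fraction8to13, 0)
  expect_true(is.na(ld2$fraction9Of8to13))

  expect_error(lengthDistribution(quickRun(character())), "empty")
})

test_that("length percentages sum to 100 on generated runs", {
  cfg <- smallConfig(seed = 31, nPeptides = 300)
  prot <- generateProteome(cfg)
  for (s in 1:3) {
    ld <- lengthDistribution(generateRun(cfg, prot, seed = s)$run)
    expect_equal(sum(ld$table$percentage), 100, tolerance = 1e-9)
    expect_lte(ld$fraction9OfAll, ld$fraction8to13)
  }
})

test_that("binder fraction saturates at the extremes", {
  # all run peptides equal the training motif: ranks at the floor -> 100%
  m <- buildPssm(rep("LLLLLLLLV", 10), pseudocount = 1e-6, allele = "A02:01")
  pred <- pssmPredictor(m, nBackground = 1000, seed = 1)
  run <- quickRun("LLLLLLLLV", haplotype = "A02:01")
  expect_equal(binderFraction(run, pred), 100)
  # peptides far below the motif: 0%
  set.seed(33)
  worst <- quickRun(c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD"),
                    haplotype = "A02:01")
  expect_equal(binderFraction(worst, pred), 0)
  # no peptide in scope -> missing value
  run15 <- quickRun("AAAAAAAAAAAAAAA", haplotype = "A02:01")
  expect_true(is.na(binderFraction(run15, pred)))
  expect_error(binderFraction(quickRun("AAAAAAAAA"), pred), "haplotype")
})

test_that("binder fraction tracks the generator's motif fraction", {
  cfg <- smallConfig(seed = 35, nPeptides = 500)
  prot <- generateProteome(cfg)
  pred <- smallPredictor(cfg, nBackground = 5000)
  g <- generateRun(cfg, prot, seed = 36)
  bf <- binderFraction(g$run, pred)
  motifPct <- 100 * mean(!g$truth$isNoise)
  expect_lt(abs(bf - motifPct), 6)
  # 9mers are enriched for motif peptides under the default design
  expect_gte(binderFraction(g$run, pred, "only_9"), bf)
})

test_that("specificity deconvolution tallies classes per allele", {
  cfg <- smallConfig(seed = 38, nPeptides = 500)
  prot <- generateProteome(cfg)
  pred <- smallPredictor(cfg, nBackground = 5000)
  run <- generateRun(cfg, prot, seed = 39)$run
  dec <- deconvoluteSpecificity(run, pred, lengths = 8:13)
  total <- sum(dec$composition$SB, dec$composition$WB) + dec$nB +
    dec$unassignable
  expect_identical(total, sum(nchar(peptideSequences(run)) %in% 8:13))
  # single-allele haplotype: every SB/WB peptide is assigned that allele
  m <- buildPssm(rep("LLLLLLLLV", 10), allele = "A02:01")
  p1 <- pssmPredictor(m, nBackground = 1000, seed = 1)
  one <- quickRun(randomPeptides(50, 9), haplotype = "A02:01")
  d1 <- deconvoluteSpecificity(one, p1)
  expect_identical(d1$composition$allele, "A02:01")
  bound <- d1$assignments$class %in% c("SB", "WB")
  expect_true(all(d1$assignments$allele[bound] == "A02:01"))
  # an unassignable 14mer under 8-13 models is counted unassignable
  mixed <- quickRun(c(randomPeptides(5, 9), "AAAAAAAAAAAAAA"),
                    haplotype = "A02:01")
  d2 <- deconvoluteSpecificity(mixed, p1, lengths = c(9L, 14L))
  expect_identical(d2$unassignable, 1L)
})

test_that("per-allele deconvolution counts match generator proportions", {
  cfg <- smallConfig(seed = 41, nPeptides = 600)
  prot <- generateProteome(cfg)
  pred <- smallPredictor(cfg, nBackground = 5000)
  g <- generateRun(cfg, prot, seed = 42)
  dec <- deconvoluteSpecificity(g$run, pred, lengths = 8:13)
  truthCounts <- table(g$truth$allele)
  for (al in dec$composition$allele) {
    got <- dec$composition$SB[dec$composition$allele == al] +
      dec$composition$WB[dec$composition$allele == al]
    expect_lt(abs(got - truthCounts[[al]]) / truthCounts[[al]], 0.10)
  }
})

test_that("exclusive overlap sets follow UpSet semantics", {
  a <- quickRun(c("AAAAAAAAA", "CCCCCCCCC"), sample = "A")
  b <- quickRun(c("CCCCCCCCC", "DDDDDDDDD"), sample = "B")
  tab <- replicateOverlapSets(list(a, b))
  get <- function(s) tab$size[tab$subset == s]
  expect_identical(get("A:r1"), 1L)
  expect_identical(get("B:r1"), 1L)
  expect_identical(get("A:r1&B:r1"), 1L)
  # identical runs: only the full subset non-zero
  b2 <- quickRun(c("AAAAAAAAA", "CCCCCCCCC"), sample = "B")
  tab2 <- replicateOverlapSets(list(a, b2))
  expect_identical(tab2$size[tab2$degree == 2], 2L)
  expect_true(all(tab2$size[tab2$degree == 1] == 0L))
  # disjoint runs: only singletons non-zero
  b3 <- quickRun(c("EEEEEEEEE", "FFFFFFFFF"), sample = "B")
  tab3 <- replicateOverlapSets(list(a, b3))
  expect_true(all(tab3$size[tab3$degree == 1] == 2L))
  expect_identical(tab3$size[tab3$degree == 2], 0L)
  expect_error(replicateOverlapSets(list(a)), "at least 2")
})

test_that("exclusive sizes sum to the union size on random run sets", {
  set.seed(44)
  for (i in 1:5) {
    pool <- randomPeptides(60, 9)
    runs <- lapply(1:4, function(j)
      quickRun(sample(pool, sample(10:40, 1)), sample = paste0("s", j)))
    tab <- replicateOverlapSets(runs)
    uni <- length(unique(unlist(lapply(runs, peptideSequences))))
    expect_identical(sum(tab$size), uni)
  }
})

test_that("motif summaries hit the entropy limits and closed forms", {
  same <- motifSummary(list(g = rep("SIINFEKLV", 15)))$g
  expect_equal(same$informationContent, rep(log2(20), 9), tolerance = 1e-12)
  expect_equal(colSums(same$freq), rep(1, 9))
  # one full cycle of the alphabet at every position: uniform -> 0 bits
  cyc <- vapply(0:19, function(k)
    paste(AA20[(k + 0:8) %% 20 + 1], collapse = ""), character(1))
  unif <- motifSummary(list(g = cyc))$g
  expect_equal(unif$informationContent, rep(0, 9), tolerance = 1e-12)
  # anchor at 0.9/0.1 concentration: closed-form entropy at position 2
  peps <- c(rep("ALAAAAAAA", 9), "ACAAAAAAA")
  anch <- motifSummary(list(g = peps))$g
  expect_equal(anch$informationContent[2],
               log2(20) + 0.9 * log2(0.9) + 0.1 * log2(0.1))
  # insufficient group
  small <- motifSummary(list(g = rep("SIINFEKLV", 5)))$g
  expect_true(small$insufficient)
  expect_identical(small$n, 5L)
})
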