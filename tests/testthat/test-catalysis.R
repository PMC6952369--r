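test_that("structure decomposition classifies every position exactly once", {
  p <- parseStructure("((((....))))")
  expect_equal(nrow(p$loops), 1L)
  expect_equal(p$loops$start, 5L)
  expect_equal(p$loops$end, 8L)
  expect_equal(p$loops$size, 4L)

  p <- parseStructure("............")
  expect_equal(nrow(p$loops), 0L)
  expect_true(all(p$class == "unpaired"))

  # interior-loop positions are "other-unpaired", not hairpin members
  p <- parseStructure("((..((...))..))")
  expect_equal(nrow(p$loops), 1L)
  expect_equal(p$loops$start, 7L)
  expect_equal(p$loops$size, 3L)
  expect_equal(which(p$class == "unpaired"), c(3L, 4L, 12L, 13L))
  expect_equal(which(p$class == "hairpin"), 7:9)

  # pair table is an involution consistent with the classes
  expect_equal(p$pairTable[p$pairTable[p$pairTable > 0]],
               which(p$pairTable > 0))
  expect_error(parseStructure("(()"), "unbalanced|invalid")
})

test_that("site detection follows the activity rules on designed cases", {
  specs <- defaultActivitySpecs()
  m1 <- specs[[1]]@motif
  # E1 motif on the unpaired tail of a stable hairpin: one site, alpha = 1
  seq1 <- paste0("GGGGGAAAACCCCCAA", m1)
  db1 <- paste0("(((((....)))))", strrep(".", 2 + nchar(m1)))
  s <- detectSites(seq1, db1, specs)
  expect_equal(nrow(s), 1L)
  expect_equal(s$activity, 1L)
  expect_equal(s$alpha, 1)
  expect_equal(s$start, 17L)

  # the same motif fully base-paired: no E1 site
  n <- nchar(m1)
  seq2 <- paste0(m1, "AAAA", rnaReverseComplement(m1))
  db2 <- paste0(strrep("(", n), "....", strrep(")", n))
  expect_equal(nrow(detectSites(seq2, db2, specs)), 0L)

  # the motif inside a hairpin loop does not count as unpaired-region
  seq3 <- paste0("GGGGG", m1, "CCCCC")
  db3 <- paste0("(((((", strrep(".", n), ")))))")
  s3 <- detectSites(seq3, db3, specs)
  expect_false(any(s3$activity == 1L))

  # E2: exact motif in a size-6 loop, target 5 -> one nt deviation, alpha 0.5
  seq4 <- "GGGGGAUCGAACCCCC"
  db4 <- "(((((......)))))"
  s4 <- detectSites(seq4, db4, specs)
  expect_equal(nrow(s4), 1L)
  expect_equal(s4$activity, 2L)
  expect_equal(s4$alpha, 0.5)

  # one motif mismatch at the target loop size: the default steep penalty
  s5 <- detectSites("GGGGGAUCAACCCCC", "(((((.....)))))", specs)
  expect_equal(s5$alpha[s5$activity == 2L], 0.25)
  # a 0.5-per-mismatch schedule applies its multiplicative penalty once
  tol <- list(activitySpec(2L, "hairpin-loop", "AUCG", targetLoopSize = 5L,
                           mismatchFactor = 0.5, maxMismatch = 1L))
  s6 <- detectSites("GGGGGAUCAACCCCC", "(((((.....)))))", tol)
  expect_equal(s6$alpha, 0.5)
  # two mismatches exceed the tolerance under either schedule
  s7 <- detectSites("GGGGGAUAAACCCCC", "(((((.....)))))", tol)
  expect_equal(nrow(s7), 0L)
})

test_that("exhaustive scan oracle reproduces site detection on random strands", {
  specs <- defaultActivitySpecs()
  bk <- toyFoldingBackend()
  set.seed(512)
  seqs <- random_rna(500, 15, 30)
  folds <- foldSequences(seqs, bk)
  for (i in seq_along(seqs)) {
    got <- detectSites(seqs[i], folds$structure[i], specs)
    got <- got[order(got$activity, got$start), , drop = FALSE]
    want <- oracle_sites(seqs[i], folds$structure[i], specs)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)),
                 tolerance = 1e-12,
                 label = sprintf("sites for %s / %s", seqs[i], folds$structure[i]))
  }
})

test_that("promiscuity penalty divides activities sub-additively", {
  one_site <- data.frame(activity = 2L, start = 6L, end = 9L, alpha = 1)
  expect_equal(strandActivity(0.8, one_site, m = 2), c(0, 0.8, 0))
  two_sites <- data.frame(activity = c(1L, 2L), start = c(1L, 10L),
                          end = c(5L, 13L), alpha = c(1, 1))
  # sigma = 2: both activities divided by m^(sigma-1) = 2
  expect_equal(strandActivity(1, two_sites, m = 2), c(0.5, 0.5, 0))
  empty <- data.frame(activity = integer(), start = integer(),
                      end = integer(), alpha = numeric())
  expect_equal(strandActivity(0.9, empty), c(0, 0, 0))
  # two sites of the same activity: sigma = 2, best alpha only
  twin <- data.frame(activity = c(2L, 2L), start = c(6L, 20L),
                     end = c(9L, 23L), alpha = c(1, 0.5))
  expect_equal(strandActivity(1, twin, m = 2), c(0, 0.5, 0))
  expect_error(strandActivity(0.5, one_site, m = 0.5), "m must be")
})

test_that("E1 activity is binary at the alpha level and bounded by pfold", {
  p <- test_params()
  set.seed(33)
  ann <- annotateStrands(random_rna(300), p)
  # a_i <= pfold always; E1 alpha is 0 or 1, so a1/pfold is 0 or 1/m^(sigma-1)
  expect_true(all(ann$a1 <= ann$pfold + 1e-12))
  expect_true(all(ann$a2 <= ann$pfold + 1e-12))
  expect_true(all(ann$a3 <= ann$pfold + 1e-12))
  mono1 <- ann$sigma == 1 & ann$a1 > 0
  expect_true(all(abs(ann$a1[mono1] - ann$pfold[mono1]) < 1e-12))
})

test_that("complementary pairs are classified on the activity grid", {
  p <- test_params()
  tpl <- generatorTemplates(p)
  ann <- function(s) annotateStrands(s, p)
  pairify <- function(s) {
    classifyPair(ann(s), ann(rnaReverseComplement(s)))
  }
  # parasite pair
  set.seed(61)
  para <- "AAAAAAAAAAAAAAA"
  expect_equal(pairify(para)$category, "parasite")
  expect_equal(pairify(para)$label, "P<->P")
  # single-activity pair: E1 on the plus strand only
  p1 <- pairify(tpl[["E1"]])
  expect_equal(p1$category, "single")
  expect_match(p1$label, "^E1<->")
  # trans-heteroactive constructed pair: E1 on plus, E2 on its complement
  a <- ann(tpl[["E1"]]); b <- ann(tpl[["E2"]])
  expect_equal(classifyPair(a, b)$category, "trans-heteroactive")
  expect_equal(classifyPair(a, a)$category, "trans-homoactive")
  # symmetric under strand swap up to label transposition
  expect_equal(classifyPair(b, a)$category, "trans-heteroactive")
  expect_equal(classifyPair(b, a)$label, "E2<->E1")
  # cis: two sites on one strand
  cis <- data.frame(a1 = 0.4, a2 = 0.4, a3 = 0, sigma = 2L, class = "cis")
  par <- data.frame(a1 = 0, a2 = 0, a3 = 0, sigma = 0L, class = "P")
  expect_equal(classifyPair(cis, par)$category, "cis-heteroactive")
  cis2 <- data.frame(a1 = 0, a2 = 0.4, a3 = 0, sigma = 2L, class = "cis")
  expect_equal(classifyPair(par, cis2)$category, "cis-homoactive")
})
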