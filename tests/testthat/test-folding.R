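test_that("folding probability is the two-state Boltzmann logistic", {
  expect_identical(foldingProbability(0, 0.3), 0.5)
  # high-precision evaluation of the logistic at cE = -7.5
  expect_equal(foldingProbability(-25, 0.3), 1 / (1 + exp(-7.5)), tolerance = 1e-15)
  expect_lt(foldingProbability(1e4), 1e-300)
  # strictly decreasing in E, range (0,1), for a grid of (E, c)
  for (cc in c(0.1, 0.3, 1)) {
    E <- seq(-30, 10, by = 0.5)
    p <- foldingProbability(E, cc)
    expect_true(all(diff(p) < 0))
    expect_true(all(p > 0 & p < 1))
  }
  expect_error(foldingProbability(0, c = -1), "c must be")
})

test_that("degradation probability is affine with clamped endpoints", {
  ep <- energyParams(delta0 = 0.2, delta1 = 0.1)
  expect_equal(degradationProbability(0, ep), 0.2)
  expect_equal(degradationProbability(-25, ep), 0.1)
  expect_equal(degradationProbability(-12.5, ep), 0.15)
  # energies below Emin are clamped, keeping p_deg in range
  expect_equal(degradationProbability(-40, ep), 0.1)
  E <- seq(-25, 0, by = 0.25)
  p <- degradationProbability(E, ep)
  expect_true(all(p >= 0.1 & p <= 0.2))
  expect_true(all(diff(p) > 0))  # lower E -> lower p_deg
  expect_error(energyParams(delta0 = 0.1, delta1 = 0.2), "delta0 > delta1")
})

test_that("replicability decreases with folding probability and length", {
  ep <- energyParams(g = 1, l = 0.1, b1 = 1, b2 = 0.01)
  expect_equal(replicability(0.5, 40, ep), 0.6 / 1.4)
  # fully folded strand retains the residual g*l/(b1+b2*L)
  expect_equal(replicability(1, 40, ep), 0.1 / 1.4)
  expect_gt(replicability(0.7, 35, ep), replicability(0.7, 45, ep))
  expect_gt(replicability(0.2, 40, ep), replicability(0.9, 40, ep))
  expect_true(all(replicability(runif(50), sample(15:75, 50, TRUE), ep) > 0))
})

test_that("reverse complement is a Watson-Crick involution", {
  expect_identical(rnaReverseComplement("AUGC"), "GCAU")
  expect_identical(rnaReverseComplement("AAAA"), "UUUU")
  set.seed(421)
  seqs <- random_rna(25)
  expect_identical(rnaReverseComplement(rnaReverseComplement(seqs)), seqs)
  # plain complement option
  expect_identical(rnaReverseComplement("AUGC", reverse = FALSE), "UACG")
  # a palindrome equals its own reverse complement
  expect_identical(rnaReverseComplement("AGCU"), "AGCU")
  expect_error(rnaReverseComplement("AUXG"), "alphabet")
})

test_that("toy backend folds deterministically and pairs a designed hairpin", {
  bk <- toyFoldingBackend()
  f <- foldSequences(c("AAAAAAAAAAAAAAA", "GGGGGAAAACCCCC"), bk)
  # no complementary bases: open chain at zero energy
  expect_identical(f$structure[1], strrep(".", 15))
  expect_identical(f$energy[1], 0)
  # GC-rich hairpin: paired stem, negative energy
  expect_identical(f$structure[2], "(((((....)))))")
  expect_lt(f$energy[2], 0)
  # determinism: repeated calls on random sequences are identical
  set.seed(99)
  seqs <- random_rna(100)
  f1 <- foldSequences(seqs, bk)
  f2 <- foldSequences(seqs, bk)
  expect_identical(f1, f2)
  expect_true(all(f1$energy <= 0))
  expect_error(foldSequences("ACGT", bk), "alphabet")
})

test_that("fold cache is transparent", {
  bk <- toyFoldingBackend()
  set.seed(100)
  seqs <- random_rna(40)
  cache <- new.env(parent = emptyenv())
  warm <- foldSequences(seqs, bk, cache)       # fills the cache
  cached <- foldSequences(seqs, bk, cache)     # pure lookups
  uncached <- foldSequences(seqs, bk)
  expect_identical(warm, uncached)
  expect_identical(cached, uncached)
  expect_identical(sort(ls(cache, all.names = TRUE)), sort(unique(seqs)))
})

test_that("ViennaRNA backend agrees with RNAfold on a designed hairpin", {
  bk <- viennaFoldingBackend()
  f <- foldSequences("GGGGGAAAACCCCC", bk)
  expect_identical(f$structure, "(((((....)))))")
  expect_lt(f$energy, 0)
  # determinism across calls
  expect_identical(foldSequences("GGGGGAAAACCCCC", bk), f)
})
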