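test_that("lattice summaries are exact counts and means", {
  p <- test_params()
  tpl <- generatorTemplates(p)
  para <- "AAAAAAAAAAAAAAA"
  grid <- matrix("", 12, 12)
  grid[1, 1] <- tpl[["E1"]]; grid[2, 1] <- tpl[["E1"]]
  grid[3, 1] <- para;        grid[4, 1] <- para
  lat <- make_lattice(grid, p)
  s <- summarizeLattice(lat)
  expect_equal(s$population, 4L)
  expect_equal(s$freqE1, 2 / 144)
  expect_equal(s$freqP, 2 / 144)
  expect_equal(s$freqE2 + s$freqE3 + s$freqCis, 0)
  # hand-computed means over the occupied sites
  ann <- annotateStrands(c(tpl[["E1"]], para), p)
  expect_equal(s$meanLength, mean(rep(ann$length, each = 2)))
  expect_equal(s$meanR, mean(rep(ann$R, each = 2)))
  expect_equal(s$meanEnergy, mean(rep(ann$energy, each = 2)))
  expect_equal(s$meanA1, ann$a1[1])  # mean over carriers only
  # empty lattice -> zero record
  z <- summarizeLattice(make_lattice(matrix("", 12, 12), p))
  expect_equal(z$population, 0L)
  expect_equal(z$meanLength, 0)
})

test_that("pair matrix tabulates complementary-strand classes", {
  p <- test_params()
  tpl <- generatorTemplates(p)
  para <- "AAAAAAAAAAAAAAA"
  # all parasites: all mass at (P, P); A-runs are self-complement parasites
  g1 <- matrix("", 12, 12); g1[1:4, 1] <- para
  m1 <- pairMatrix(make_lattice(g1, p))
  expect_equal(sum(m1), 1)
  expect_equal(m1["P", "P"], 1)
  # mixed population of known composition against hand tabulation
  g2 <- matrix("", 12, 12)
  g2[1:2, 1] <- tpl[["E1"]]; g2[3, 1] <- tpl[["E2"]]; g2[4:5, 1] <- para
  m2 <- pairMatrix(make_lattice(g2, p))
  expect_equal(sum(m2), 1)
  annM <- annotateStrands(rnaReverseComplement(unname(tpl)), p)
  c1 <- annM$class[1]  # complement class of the E1 template
  c2 <- annM$class[2]
  expect_equal(unname(m2["E1", c1]), 2 / 5)
  expect_equal(unname(m2["E2", c2]), 1 / 5)
  expect_equal(unname(m2["P", "P"]), 2 / 5)
  # marginals over strand classes agree with the summary frequencies
  s <- summarizeLattice(make_lattice(g2, p))
  expect_equal(unname(rowSums(m2)["E1"]) * 5 / 144, s$freqE1)
})

test_that("energy histogram masses sum to class frequencies", {
  p <- test_params()
  tpl <- generatorTemplates(p)
  grid <- matrix("", 12, 12)
  grid[1:3, 1] <- tpl[["E2"]]; grid[4:5, 1] <- "AAAAAAAAAAAAAAA"
  lat <- make_lattice(grid, p)
  h <- energyHistogram(lat, binWidth = 1)
  expect_equal(sum(h$mass), 1)
  s <- summarizeLattice(lat)
  byclass <- tapply(h$mass, as.character(h$class), sum)
  expect_equal(unname(byclass["E2"]), s$freqE2 * 144 / s$population)
  expect_equal(unname(byclass["P"]), s$freqP * 144 / s$population)
})

test_that("edit distances satisfy metric axioms and match the DP oracle", {
  expect_equal(distanceMatrix(c("AAAA", "AAAA"))[1, 2], 0)
  expect_equal(distanceMatrix(c("AAAA", "AAAU"))[1, 2], 1)
  expect_equal(distanceMatrix(c("AAAA", "AAA"))[1, 2], 1)
  set.seed(1009)
  seqs <- random_rna(40, 10, 30)
  d <- distanceMatrix(seqs)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  # 200 random pairs against the dynamic-programming oracle
  pairs <- cbind(sample.int(40, 200, TRUE), sample.int(40, 200, TRUE))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    expect_identical(d[i, j], dp_edit_distance(seqs[i], seqs[j]))
  }
  # triangle inequality on all triples of a small sample
  for (i in 1:10) for (j in 1:10) for (k in 1:10)
    expect_lte(d[i, j], d[i, k] + d[k, j])
})

test_that("classical scaling recovers Euclidean configurations", {
  # three collinear points with distances 1, 1, 2: one axis, spacing 1
  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  fit <- pcoaCoordinates(d3, k = 1)
  x <- sort(fit$points[, 1])
  expect_equal(diff(x), c(1, 1), tolerance = 1e-9)
  expect_true(all(fit$eig >= 0))
  # degenerate all-zero distances: all points at the origin
  z <- pcoaCoordinates(matrix(0, 4, 4), k = 2)
  expect_equal(unname(z$points), matrix(0, 4, 2))
  # generate-and-recover: distances from random planar points
  set.seed(77)
  pts <- matrix(rnorm(40), ncol = 2)
  d <- as.matrix(dist(pts))
  rec <- pcoaCoordinates(d, k = 2)$points
  expect_equal(as.numeric(dist(rec)), as.numeric(dist(pts)), tolerance = 1e-8)
})

test_that("sequence sampling draws from the occupants", {
  p <- test_params()
  set.seed(5)
  lat <- initPopulation(p)
  s <- sampleSequences(lat, 30)
  expect_length(s, 30)
  expect_true(all(s %in% occupiedSequences(lat)))
  expect_error(sampleSequences(make_lattice(matrix("", 12, 12), p)), "empty")
})
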