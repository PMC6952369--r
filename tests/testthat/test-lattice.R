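test_that("initialization realizes the layered random allocation", {
  p <- test_params(width = 40, height = 40)
  # occupancy 0 -> empty lattice
  set.seed(5)
  empty <- initPopulation(test_params(occupancy = 0))
  expect_equal(occupiedFraction(empty), 0)
  # same seed -> identical lattices
  set.seed(17)
  a <- initPopulation(p)
  set.seed(17)
  b <- initPopulation(p)
  expect_identical(a@grid, b@grid)
  # occupancy close to its expectation; actives are template copies,
  # inactives carry no catalytic site
  set.seed(18)
  lat <- initPopulation(p)
  expect_equal(occupiedFraction(lat), 0.8, tolerance = 0.05)
  tpl <- generatorTemplates(p)
  seqs <- occupiedSequences(lat)
  ann <- annotateStrands(unique(seqs), p, lat@foldCache)
  sig <- ann$sigma[match(seqs, ann$sequence)]
  expect_true(all(seqs[sig > 0] %in% tpl))
  expect_true(all(sig[!seqs %in% tpl] == 0))
  # all three activity types present among the actives
  expect_setequal(unique(seqs[sig > 0]), unname(tpl))
})

test_that("metabolic activity is a geometric mean with a completeness veto", {
  p <- test_params()
  tpl <- generatorTemplates(p)
  grid <- matrix("", 12, 12)
  grid[5, 5] <- tpl[["E1"]]; grid[6, 5] <- tpl[["E2"]]; grid[5, 6] <- tpl[["E3"]]
  lat <- make_lattice(grid, p)
  ann <- annotateStrands(unname(tpl), p)
  a <- c(max(ann$a1), max(ann$a2), max(ann$a3))
  expect_equal(metabolicActivity(lat, 5, 5), prod(a)^(1 / 3), tolerance = 1e-12)
  # neighborhood lacking one activity type vetoes metabolism
  grid2 <- grid; grid2[6, 5] <- ""
  expect_equal(metabolicActivity(make_lattice(grid2, p), 5, 5), 0)
  # wrap-around: same trio re-centered across the torus edge
  grid3 <- matrix("", 12, 12)
  grid3[1, 1] <- tpl[["E1"]]; grid3[12, 1] <- tpl[["E2"]]; grid3[1, 12] <- tpl[["E3"]]
  expect_equal(metabolicActivity(make_lattice(grid3, p), 1, 1),
               prod(a)^(1 / 3), tolerance = 1e-12)
})

test_that("replication claims match brute-force enumeration and close to 1", {
  p <- test_params(width = 10, height = 10)
  tpl <- generatorTemplates(p)
  pool <- c(unname(tpl), "AAAAAAAAAAAAAAA", "GGGGGAAAACCCCCAA")
  set.seed(71)
  checked <- 0
  for (rep in 1:60) {
    grid <- matrix("", 10, 10)
    fill <- runif(1, 0.2, 0.8)
    occ <- runif(100) < fill
    grid[occ] <- sample(pool, sum(occ), replace = TRUE)
    lat <- make_lattice(grid, p)
    ann <- annotateStrands(unique(grid[occ]), p, lat@foldCache)
    fields <- mcrs:::.activity_fields(lat)
    empties <- which(grid == "", arr.ind = TRUE)
    if (!nrow(empties)) next
    take <- empties[sample.int(nrow(empties), min(18, nrow(empties))), ,
                    drop = FALSE]
    for (k in seq_len(nrow(take))) {
      x <- take[k, 1]; y <- take[k, 2]
      got <- replicationClaims(lat, x, y)
      # independent enumeration: C_f = M_f * R_f over the 8 neighbors
      wrap <- function(i, n) ((i - 1) %% n) + 1
      cl <- numeric(0)
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0 && dy == 0) next
        nx <- wrap(x + dx, 10); ny <- wrap(y + dy, 10)
        s <- grid[nx, ny]
        if (s == "") next
        M <- metabolicActivity(lat, nx, ny, fields)
        if (M <= 0) next
        C <- M * ann$R[match(s, ann$sequence)]
        if (C > 0) cl <- c(cl, C)
      }
      tot <- p@claimEmpty + sum(cl)
      expect_equal(sum(got$claimants$probability) + got$stayEmpty, 1,
                   tolerance = 1e-12)
      expect_equal(got$stayEmpty, p@claimEmpty / tot, tolerance = 1e-12)
      expect_equal(sort(got$claimants$probability), sort(cl / tot),
                   tolerance = 1e-12)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 1000)
  # no occupied neighbors -> site stays empty with probability 1
  lone <- make_lattice(matrix("", 10, 10), p)
  expect_equal(replicationClaims(lone, 3, 3)$stayEmpty, 1)
})

test_that("replication synthesizes the mutated reverse complement", {
  p0 <- test_params(pSub = 0, pIns = 0, pDel = 0)
  set.seed(3)
  seqs <- random_rna(20)
  for (s in seqs)
    expect_identical(replicateWithMutation(s, p0), rnaReverseComplement(s))
  # certain deletion shrinks the product below the length bound
  expect_true(is.na(replicateWithMutation(seqs[1], test_params(pDel = 1))))
  # substitution count is Binomial(L, pSub): check the Monte-Carlo mean
  ps <- test_params(pSub = 0.01, pIns = 0, pDel = 0)
  tmpl <- paste(rep("A", 40), collapse = "")
  want <- rnaReverseComplement(tmpl)
  set.seed(8)
  nsub <- vapply(1:20000, function(i) {
    out <- replicateWithMutation(tmpl, ps)
    sum(strsplit(out, "")[[1]] != strsplit(want, "")[[1]])
  }, numeric(1))
  se <- sqrt(40 * 0.01 * 0.99 / 20000)
  expect_lt(abs(mean(nsub) - 0.4), 3 * se)
})

test_that("engine mutation rates match their binomial expectations", {
  # the compiled generation loop draws per-base mutation events; over a
  # sustained run the substitutions-per-replication ratio is pSub times the
  # mean template length
  p <- simParams(width = 10, height = 10, pSub = 0.02, pIns = 0, pDel = 0)
  tpl <- generatorTemplates(p)
  grid <- matrix(rep_len(unname(tpl), 100), 10, 10)
  set.seed(55)
  lat <- make_lattice(grid, p)
  out <- runSimulation(lat, 600, recordEvery = 5)
  ev <- out$events
  reps <- sum(ev$replications)
  expect_gt(reps, 300)
  tr <- out$trajectory
  meanL <- mean(tr$meanLength[tr$population > 0])
  got <- sum(ev$substitutions) / reps
  expect_equal(got, meanL * 0.02, tolerance = 0.2)
})

test_that("Margolus diffusion permutes occupants and conserves the multiset", {
  p <- test_params(width = 16, height = 16)
  set.seed(23)
  lat <- initPopulation(p)
  # D = 0 is the identity
  lat0 <- diffuse(lat, D = 0)
  expect_identical(lat0@grid, lat@grid)
  # any D: occupant multiset exactly conserved
  cur <- lat
  before <- sort(occupiedSequences(lat))
  for (i in 1:50) {
    cur <- diffuse(cur, D = 1.7)
    expect_identical(sort(occupiedSequences(cur)), before)
  }
  expect_false(identical(cur@grid, lat@grid))
  # odd grid dimension is a configuration error
  expect_error(cpp_diffuse(1:15, 3L, 5L, 1, 0L), "even grid")
})

test_that("single-occupant diffusion behaves as an unbiased random walk", {
  # one occupant, many sweeps: displacement is unbiased and the mean squared
  # displacement grows linearly in sweep count
  p <- test_params(width = 40, height = 40)
  msd <- function(sweeps, nrep) {
    d2 <- numeric(nrep)
    for (r in seq_len(nrep)) {
      grid <- matrix("", 40, 40)
      grid[20, 20] <- "AAAAAAAAAAAAAAA"
      lat <- make_lattice(grid, p)
      for (s in seq_len(sweeps)) lat <- diffuse(lat, D = 1)
      pos <- which(lat@grid != "", arr.ind = TRUE)
      d2[r] <- sum((pos - c(20, 20))^2)
    }
    mean(d2)
  }
  set.seed(301)
  m8 <- msd(8, 400)
  m32 <- msd(32, 400)
  # linear growth: quadrupling the sweeps ~ quadruples the MSD
  expect_equal(m32 / m8, 4, tolerance = 0.35)
})

test_that("a generation performs W*H updates and respects degradation", {
  # immortal strands, full lattice: state unchanged up to the diffusion
  # permutation
  p <- simParams(width = 10, height = 10, occupancy = 1, activeFraction = 1,
                 energy = energyParams(delta0 = 1e-12, delta1 = 0),
                 pSub = 0, pIns = 0, pDel = 0)
  tpl <- generatorTemplates(p)
  grid <- matrix(sample(unname(tpl), 100, replace = TRUE), 10, 10)
  set.seed(41)
  lat <- make_lattice(grid, p)
  s <- stepGeneration(lat)
  expect_equal(s$events$updates, 100L)
  expect_equal(s$events$degradations, 0L)
  expect_identical(sort(occupiedSequences(s$lattice)), sort(as.vector(grid)))
  # certain degradation, no metabolic support: empty after one generation.
  # delta0 = 1 requires delta1 < 1; use a parasite at E = 0 so p_deg = 1.
  p2 <- test_params(width = 10, height = 10,
                    energy = energyParams(delta0 = 1, delta1 = 0.5))
  grid2 <- matrix("", 10, 10)
  grid2[4, 4] <- "AAAAAAAAAAAAAAA"
  set.seed(42)
  lat2 <- make_lattice(grid2, p2)
  out2 <- runSimulation(lat2, 8, recordEvery = 0)
  expect_equal(occupiedFraction(out2$lattice), 0)
})

test_that("removing one activity type vetoes all replication globally", {
  p <- test_params(width = 16, height = 16)
  tpl <- generatorTemplates(p)
  set.seed(77)
  # E3 carriers removed everywhere: metabolism is incomplete at every site
  grid <- matrix("", 16, 16)
  occ <- runif(256) < 0.8
  grid[occ] <- sample(c(tpl[["E1"]], tpl[["E2"]]), sum(occ), replace = TRUE)
  lat <- make_lattice(grid, p)
  out <- runSimulation(lat, 60, recordEvery = 0)
  expect_equal(sum(out$events$replications), 0L)
  # and the system decays towards empty
  expect_lt(occupiedFraction(out$lattice), occupiedFraction(lat))
})

test_that("runs are reproducible from the seed alone", {
  p <- test_params(width = 16, height = 16)
  run <- function() {
    set.seed(1234)
    lat <- initPopulation(p)
    runSimulation(lat, 40, recordEvery = 5)
  }
  a <- run()
  b <- run()
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$events, b$events)
  expect_identical(a$lattice@grid, b$lattice@grid)
})

test_that("compiled engine matches a plain-R reference on a small torus", {
  # expected occupancy change over one generation, compared by Monte Carlo
  # between the compiled engine and an independent R implementation of the
  # update rules (mutation off, diffusion irrelevant to occupancy)
  p <- simParams(width = 6, height = 6, pSub = 0, pIns = 0, pDel = 0,
                 diffusion = 0)
  tpl <- generatorTemplates(p)
  set.seed(90)
  grid <- matrix("", 6, 6)
  occ <- runif(36) < 0.6
  grid[occ] <- sample(c(unname(tpl), "AAAAAAAAAAAAAAA"), sum(occ), replace = TRUE)
  pool <- unique(c(grid[grid != ""], rnaReverseComplement(grid[grid != ""])))
  ann <- annotateStrands(pool, p)
  n_mc <- 1200
  d_eng <- numeric(n_mc)
  d_ref <- numeric(n_mc)
  lat0 <- make_lattice(grid, p)
  occ0 <- sum(grid != "")
  for (i in seq_len(n_mc)) {
    s <- stepGeneration(lat0)
    d_eng[i] <- sum(s$lattice@grid != "") - occ0
    d_ref[i] <- sum(reference_generation(grid, p, ann) != "") - occ0
  }
  se <- sqrt(var(d_eng) / n_mc + var(d_ref) / n_mc)
  expect_lt(abs(mean(d_eng) - mean(d_ref)), 4 * se + 1e-9)
})
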