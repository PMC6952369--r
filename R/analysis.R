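#' Summarize a lattice state
#'
#' Exact counts and means over the occupied sites: strand-class frequencies
#' (relative to the whole grid, so they sum to the occupied fraction), mean
#' length, mean replicability, mean free energy, mean folding probability
#' and mean actual activity per activity type (over carriers of that
#' activity). An empty lattice yields a zero record.
#'
#' @param lat a [ReplicatorLattice-class].
#' @return a one-row `data.frame` with the same columns as a
#'   [runSimulation()] trajectory record.
#' @export
summarizeLattice <- function(lat) {
  stopifnot(is(lat, "ReplicatorLattice"))
  seqs <- occupiedSequences(lat)
  N <- length(lat@grid)
  zero <- data.frame(t = lat@generation, population = 0L, freqE1 = 0,
                     freqE2 = 0, freqE3 = 0, freqP = 0, freqCis = 0,
                     meanLength = 0, meanR = 0, meanEnergy = 0,
                     meanPfold = 0, meanA1 = 0, meanA2 = 0, meanA3 = 0)
  if (!length(seqs)) return(zero)
  uq <- unique(seqs)
  ann <- annotateStrands(uq, lat@params, lat@foldCache)
  ann <- ann[match(seqs, ann$sequence), ]
  meanA <- function(k) {
    a <- ann[[paste0("a", k)]]
    carriers <- a > 0
    if (any(carriers)) mean(a[carriers]) else 0
  }
  data.frame(
    t = lat@generation, population = length(seqs),
    freqE1 = sum(ann$class == "E1") / N, freqE2 = sum(ann$class == "E2") / N,
    freqE3 = sum(ann$class == "E3") / N, freqP = sum(ann$class == "P") / N,
    freqCis = sum(ann$class == "cis") / N,
    meanLength = mean(ann$length), meanR = mean(ann$R),
    meanEnergy = mean(ann$energy), meanPfold = mean(ann$pfold),
    meanA1 = meanA(1), meanA2 = meanA(2), meanA3 = meanA(3)
  )
}

.pair_classes <- c("P", "E1", "E2", "E3", "cis")

#' Activity-pair matrix of complementary strands
#'
#' For every occupied site the resident strand and its reverse complement
#' are annotated and classified; the relative frequency of each (strand
#' class, complement class) combination is accumulated over the population.
#' Each occupied site contributes one pair (resident as "strand", reverse
#' complement as "complement"); the matrix is reported as-is, not folded
#' over the diagonal.
#'
#' @param lat a [ReplicatorLattice-class].
#' @return a 5 x 5 matrix over classes P, E1, E2, E3, cis; entries are
#'   non-negative and sum to 1 (all zero for an empty lattice).
#' @export
pairMatrix <- function(lat) {
  stopifnot(is(lat, "ReplicatorLattice"))
  M <- matrix(0, 5, 5, dimnames = list(strand = .pair_classes,
                                       complement = .pair_classes))
  seqs <- occupiedSequences(lat)
  if (!length(seqs)) return(M)
  uq <- unique(seqs)
  annP <- annotateStrands(uq, lat@params, lat@foldCache)
  annM <- annotateStrands(rnaReverseComplement(uq), lat@params, lat@foldCache)
  cp <- factor(annP$class, levels = .pair_classes)[match(seqs, uq)]
  cm <- factor(annM$class, levels = .pair_classes)[match(seqs, uq)]
  tab <- table(cp, cm)
  M[] <- as.numeric(tab) / length(seqs)
  M
}

#' Free-energy histograms by strand class
#'
#' Histogram of the Gibbs free energies of the occupied strands, split by
#' strand class. Masses are relative to the occupied population, so the
#' total mass of a class equals its relative frequency among occupants.
#'
#' @param lat a [ReplicatorLattice-class].
#' @param binWidth bin width in kcal/mol.
#' @return `data.frame` with columns `class`, `mid` (bin midpoint), `count`,
#'   `mass`.
#' @export
energyHistogram <- function(lat, binWidth = 1) {
  stopifnot(is(lat, "ReplicatorLattice"), binWidth > 0)
  seqs <- occupiedSequences(lat)
  if (!length(seqs))
    return(data.frame(class = character(), mid = numeric(),
                      count = integer(), mass = numeric()))
  uq <- unique(seqs)
  ann <- annotateStrands(uq, lat@params, lat@foldCache)
  ann <- ann[match(seqs, ann$sequence), ]
  bin <- floor(ann$energy / binWidth)
  agg <- stats::aggregate(list(count = bin),
                          by = list(class = ann$class, bin = bin), FUN = length)
  data.frame(class = agg$class, mid = (agg$bin + 0.5) * binWidth,
             count = agg$count, mass = agg$count / length(seqs))
}

#' Pairwise edit-distance matrix
#'
#' Levenshtein edit distances between all pairs of sequences. Insertion and
#' deletion mutations make strand lengths unequal, so the edit distance is
#' used as the sequence dissimilarity; for equal-length sequences without
#' indels it coincides with the Hamming distance.
#'
#' @param seqs character vector of at least two sequences.
#' @return symmetric integer matrix with zero diagonal; the triangle
#'   inequality holds.
#' @export
distanceMatrix <- function(seqs) {
  if (length(seqs) < 2) stop("need at least two sequences", call. = FALSE)
  d <- utils::adist(seqs)
  dimnames(d) <- NULL
  d
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical (Torgerson) scaling: double-centering of the squared
#' distances and eigendecomposition, keeping the top `k` coordinates.
#' Negative eigenvalues (non-Euclidean residuals of the edit distance) are
#' truncated to zero. For a Euclidean-embeddable input the recovered
#' inter-point distances match the input.
#'
#' @param d symmetric distance matrix.
#' @param k number of coordinate axes.
#' @return a list with `points` (n x k coordinate matrix) and `eig`
#'   (eigenvalues, negative values set to zero).
#' @export
pcoaCoordinates <- function(d, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k >= n) stop("k must be smaller than the number of points", call. = FALSE)
  fit <- suppressWarnings(stats::cmdscale(d, k = k, eig = TRUE))
  pts <- fit$points
  if (is.null(dim(pts)) || ncol(pts) < k) {
    # degenerate inputs (e.g. all-zero distances) may yield fewer axes
    full <- matrix(0, n, k)
    if (!is.null(dim(pts)) && ncol(pts) > 0) full[, seq_len(ncol(pts))] <- pts
    pts <- full
  }
  list(points = pts, eig = pmax(fit$eig, 0))
}

#' Sample sequences from a lattice
#'
#' Random sample (without replacement when possible) of occupied-site
#' sequences, the input for distance-based community analyses.
#'
#' @param lat a [ReplicatorLattice-class].
#' @param n sample size.
#' @return character vector of sequences.
#' @export
sampleSequences <- function(lat, n = 1000) {
  seqs <- occupiedSequences(lat)
  if (!length(seqs)) stop("lattice is empty", call. = FALSE)
  seqs[sample.int(length(seqs), min(n, length(seqs)))]
}
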