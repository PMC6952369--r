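#' Construct an activity specification
#'
#' @param index activity index (1, 2 or 3).
#' @param context `"unpaired-region"` or `"hairpin-loop"`.
#' @param motif recognition motif (5 bases for the unpaired-region activity,
#'   4 bases for hairpin-loop activities).
#' @param targetLoopSize target hairpin-loop size, nt.
#' @param mismatchFactor multiplicative penalty per motif mismatch.
#' @param maxMismatch maximum tolerated mismatches.
#' @param loopSizeFactor multiplicative penalty per nt of loop-size deviation.
#' @param maxLoopDeviation maximum tolerated deviation, nt.
#' @return an [ActivitySpec-class].
#' @export
activitySpec <- function(index, context, motif, targetLoopSize = nchar(motif),
                         mismatchFactor = 0.5, maxMismatch = 1L,
                         loopSizeFactor = 0.5, maxLoopDeviation = 2L) {
  new("ActivitySpec", index = as.integer(index), context = context,
      motif = motif, targetLoopSize = as.integer(targetLoopSize),
      mismatchFactor = mismatchFactor, maxMismatch = as.integer(maxMismatch),
      loopSizeFactor = loopSizeFactor,
      maxLoopDeviation = as.integer(maxLoopDeviation))
}

#' Default activity specifications
#'
#' The three metabolic activities of the model. E1 is an exact ("binary")
#' 5-base motif in non-paired positions outside hairpin loops: no mismatch is
#' tolerated, so its specific activity is 0 or 1. E2 and E3 are 4-base motifs
#' inside hairpin loops of target sizes 5 and 9 nt, with a steep
#' multiplicative penalty of 0.25 per motif mismatch (at most 1 tolerated)
#' and 0.5 per nt of loop-size deviation (at most 2). The mismatch penalty is
#' deliberately steep: catalytic function must be rare and weak in random
#' sequence (otherwise accidental activity in mutational noise keeps
#' metabolism running and no error threshold exists) while still degrading
#' gracefully under point mutation. All values are configurable.
#'
#' @return list of three [ActivitySpec-class] objects.
#' @examples
#' defaultActivitySpecs()
#' @export
defaultActivitySpecs <- function() {
  list(
    activitySpec(1L, "unpaired-region", "GUGGA", targetLoopSize = 5L,
                 maxMismatch = 0L),
    activitySpec(2L, "hairpin-loop", "AUCG", targetLoopSize = 5L,
                 mismatchFactor = 0.25, maxMismatch = 1L),
    activitySpec(3L, "hairpin-loop", "GGAC", targetLoopSize = 9L,
                 mismatchFactor = 0.25, maxMismatch = 1L)
  )
}

.spec_as_list <- function(s) {
  list(index = s@index, context = s@context, motif = s@motif,
       targetLoopSize = s@targetLoopSize, mismatchFactor = s@mismatchFactor,
       maxMismatch = s@maxMismatch, loopSizeFactor = s@loopSizeFactor,
       maxLoopDeviation = s@maxLoopDeviation)
}

.specs_as_list <- function(specs) lapply(specs, .spec_as_list)

.energy_as_list <- function(e) {
  list(c = e@c, delta0 = e@delta0, delta1 = e@delta1, Emin = e@Emin,
       g = e@g, l = e@l, b1 = e@b1, b2 = e@b2)
}

#' Decompose a dot-bracket structure
#'
#' Classifies every position of a balanced dot-bracket string exactly once as
#' paired, hairpin-loop member, or other-unpaired (exterior, bulge, interior
#' or multiloop positions). A hairpin loop is a maximal run of unpaired
#' positions directly enclosed by a base pair with no pair inside.
#'
#' @param structure a dot-bracket string.
#' @return a list with `pairTable` (1-based pairing partner, 0 if unpaired),
#'   `class` (factor: `"paired"`, `"hairpin"`, `"unpaired"`), and `loops`
#'   (`data.frame` of hairpin loops with 1-based `start`, `end`, `size`).
#' @examples
#' parseStructure("((((....))))")$loops
#' @export
parseStructure <- function(structure) {
  stopifnot(is.character(structure), length(structure) == 1L)
  r <- cpp_parse_structure(structure)
  r$class <- factor(c("paired", "hairpin", "unpaired")[r$class + 1L],
                    levels = c("paired", "hairpin", "unpaired"))
  r
}

#' Detect catalytic sites on a folded strand
#'
#' Applies the activity rules to a (sequence, structure) pair: the
#' unpaired-region activity requires its motif fully inside a maximal run of
#' non-paired, non-hairpin positions; hairpin activities score the best
#' motif window inside each hairpin loop with multiplicative mismatch and
#' loop-size penalties. At most one site is reported per activity and
#' structural element (the highest-alpha placement, ties to the leftmost);
#' sites with specific activity 0 are not emitted.
#'
#' @param seq RNA sequence.
#' @param structure its dot-bracket structure (same length).
#' @param specs list of [ActivitySpec-class] objects.
#' @return `data.frame` with columns `activity`, `start`, `end`, `alpha`
#'   (1-based inclusive positions); zero rows when nothing is found.
#' @export
detectSites <- function(seq, structure, specs = defaultActivitySpecs()) {
  .check_rna(seq)
  stopifnot(length(seq) == 1L, nchar(seq) == nchar(structure))
  cpp_detect_sites(seq, structure, .specs_as_list(specs))
}

#' Actual activities of a strand
#'
#' Combines folding probability, specific site activities and the
#' cis-promiscuity penalty: a strand carrying \eqn{\sigma} catalytic sites in
#' total has each activity reduced sub-additively, \eqn{a_i = p_{fold}
#' \alpha_i / m^{\sigma - 1}}, so a mono-active strand (\eqn{\sigma = 1}) is
#' unpenalized. When two sites of the same activity are present both count
#' towards \eqn{\sigma} but only the best \eqn{\alpha} contributes.
#'
#' @param pfold folding probability of the strand.
#' @param sites site table as returned by [detectSites()].
#' @param m promiscuity penalty base, >= 1.
#' @return numeric vector `c(a1, a2, a3)`.
#' @export
strandActivity <- function(pfold, sites, m = 2) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  a <- numeric(3)
  if (nrow(sites) == 0) return(a)
  sigma <- nrow(sites)
  for (i in 1:3) {
    ai <- sites$alpha[sites$activity == i]
    if (length(ai)) a[i] <- max(ai)
  }
  pfold * a / m^(sigma - 1)
}

#' Annotate strands with their full phenotype
#'
#' Folds each sequence (memoized), detects catalytic sites and returns the
#' complete strand state used by the dynamics: energy, folding probability,
#' degradation probability, replicability, actual activities, site count and
#' strand class.
#'
#' @param seqs character vector of RNA sequences.
#' @param params a [SimParams-class] (supplies backend, energy parameters,
#'   activity specs and `m`).
#' @param cache optional fold-memo environment (e.g. the lattice's).
#' @return `data.frame` with one row per sequence: `sequence`, `structure`,
#'   `length`, `energy`, `pfold`, `pdeg`, `R`, `a1`..`a3`, `sigma`, `class`.
#'   `class` is `"P"` (no site), `"E1"`/`"E2"`/`"E3"` (mono-active) or
#'   `"cis"` (two or more sites).
#' @export
annotateStrands <- function(seqs, params = simParams(), cache = NULL) {
  stopifnot(is(params, "SimParams"))
  if (!length(seqs)) {
    return(data.frame(sequence = character(), structure = character(),
                      length = integer(), energy = numeric(), pfold = numeric(),
                      pdeg = numeric(), R = numeric(), a1 = numeric(),
                      a2 = numeric(), a3 = numeric(), sigma = integer(),
                      class = character()))
  }
  f <- foldSequences(seqs, params@backend, cache)
  ann <- cpp_annotate(f$sequence, f$structure, f$energy,
                      .energy_as_list(params@energy), params@m,
                      .specs_as_list(params@specs))
  cls <- .strand_class(ann)
  cbind(f[, c("sequence", "structure")], ann, class = cls,
        stringsAsFactors = FALSE)
}

.strand_class <- function(ann) {
  ntypes <- (ann$a1 > 0) + (ann$a2 > 0) + (ann$a3 > 0)
  cls <- rep("P", nrow(ann))
  cls[ann$sigma >= 2] <- "cis"
  mono <- ann$sigma == 1 & ntypes == 1
  cls[mono & ann$a1 > 0] <- "E1"
  cls[mono & ann$a2 > 0] <- "E2"
  cls[mono & ann$a3 > 0] <- "E3"
  cls
}

#' Classify a complementary strand pair
#'
#' Template replication alternates between the two complementary strands of
#' a replicator, so the pair is the natural unit of catalytic repertoire.
#' Classes follow the activity grid: both strands inactive (`P<->P`,
#' parasite pair), one mono-active strand (`Ei<->P`), both strands
#' mono-active in the same (`trans-homoactive`) or different
#' (`trans-heteroactive`) activities, or at least one strand carrying two or
#' more sites (`cis`, sub-classified `homo`/`hetero` by whether its sites
#' share one activity type).
#'
#' @param plus annotation row (from [annotateStrands()]) of the resident
#'   strand.
#' @param minus annotation row of its reverse complement.
#' @return a list with `label` (e.g. `"E1<->E2"`) and `category` (one of
#'   `"parasite"`, `"single"`, `"trans-homoactive"`, `"trans-heteroactive"`,
#'   `"cis-homoactive"`, `"cis-heteroactive"`).
#' @export
classifyPair <- function(plus, minus) {
  cp <- as.character(plus$class)
  cm <- as.character(minus$class)
  label <- paste0(cp, "<->", cm)
  if (cp == "cis" || cm == "cis") {
    cisrow <- if (cp == "cis") plus else minus
    ntypes <- (cisrow$a1 > 0) + (cisrow$a2 > 0) + (cisrow$a3 > 0)
    category <- if (ntypes <= 1) "cis-homoactive" else "cis-heteroactive"
  } else if (cp == "P" && cm == "P") {
    category <- "parasite"
  } else if (cp == "P" || cm == "P") {
    category <- "single"
  } else if (cp == cm) {
    category <- "trans-homoactive"
  } else {
    category <- "trans-heteroactive"
  }
  list(label = label, category = category)
}
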