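#' @useDynLib mcrs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Energy-derived dynamical parameters
#'
#' Parameters mapping the Gibbs free energy \eqn{E} of a strand's
#' minimum-free-energy structure, and its length \eqn{L}, to the three
#' dynamical quantities of the model: the folding probability
#' \eqn{p_{fold} = e^{-cE} / (1 + e^{-cE})}, the per-generation degradation
#' probability \eqn{p_{deg} = \delta_0 - \delta_1 E / E_{min}}, and the
#' replicability \eqn{R = g (l + (1 - p_{fold})) / (b_1 + b_2 L)}.
#'
#' @slot c steepness of the folding-probability logistic, 1/(kcal/mol); must
#'   be positive.
#' @slot delta0 baseline degradation probability per generation (the value at
#'   \eqn{E = 0}).
#' @slot delta1 free-energy proportionality factor of degradation;
#'   \code{delta0 > delta1 >= 0} so that no replicator is immortal.
#' @slot Emin empirical lower bound of the free energy (kcal/mol, negative);
#'   energies below it are clamped when computing \eqn{p_{deg}}.
#' @slot g overall replicability scale (dimensionless).
#' @slot l residual replicability of a fully folded strand; positive.
#' @slot b1 length-independent component of replication time.
#' @slot b2 per-nucleotide component of replication time ("length penalty").
#'
#' @seealso [energyParams()], [foldingProbability()],
#'   [degradationProbability()], [replicability()]
#' @export
setClass("EnergyParams",
  representation(
    c = "numeric", delta0 = "numeric", delta1 = "numeric", Emin = "numeric",
    g = "numeric", l = "numeric", b1 = "numeric", b2 = "numeric"
  )
)

setValidity("EnergyParams", function(object) {
  msg <- character()
  if (object@c <= 0) msg <- c(msg, "c must be > 0")
  if (object@delta1 < 0) msg <- c(msg, "delta1 must be >= 0")
  if (object@delta0 <= object@delta1)
    msg <- c(msg, "delta0 > delta1 is required (delta0 <= delta1 would allow immortal replicators)")
  if (object@delta0 > 1) msg <- c(msg, "delta0 is a probability and must be <= 1")
  if (object@Emin >= 0) msg <- c(msg, "Emin must be negative")
  if (object@g <= 0) msg <- c(msg, "g must be > 0")
  if (object@l <= 0) msg <- c(msg, "l must be > 0")
  if (object@b1 + object@b2 * 15 <= 0 || object@b1 + object@b2 * 75 <= 0)
    msg <- c(msg, "b1 + b2*L must be > 0 over the whole length interval [15, 75]")
  if (length(msg)) msg else TRUE
})

#' Specification of one catalytic activity
#'
#' Describes where on a folded strand a metabolic ribozyme activity resides
#' and how imperfections are penalized. Activity 1 requires an exact 5-base
#' motif lying entirely in non-paired positions outside hairpin loops;
#' activities 2 and 3 require a 4-base motif inside a hairpin loop of a
#' characteristic size (a smaller and a larger loop, respectively). The
#' specific activity of a site is
#' \eqn{\alpha = f_{mm}^{mismatches} \cdot f_{loop}^{|size - target|}},
#' zero beyond the tolerated maxima.
#'
#' @slot index activity index, 1, 2 or 3.
#' @slot context `"unpaired-region"` or `"hairpin-loop"`.
#' @slot motif the recognition motif (RNA alphabet).
#' @slot targetLoopSize target hairpin-loop size in nt (hairpin context only).
#' @slot mismatchFactor multiplicative penalty per motif mismatch.
#' @slot maxMismatch maximum tolerated mismatches (0 makes the activity binary).
#' @slot loopSizeFactor multiplicative penalty per nt of loop-size deviation.
#' @slot maxLoopDeviation maximum tolerated loop-size deviation in nt.
#'
#' @seealso [activitySpec()], [defaultActivitySpecs()], [detectSites()]
#' @export
setClass("ActivitySpec",
  representation(
    index = "integer", context = "character", motif = "character",
    targetLoopSize = "integer", mismatchFactor = "numeric",
    maxMismatch = "integer", loopSizeFactor = "numeric",
    maxLoopDeviation = "integer"
  )
)

setValidity("ActivitySpec", function(object) {
  msg <- character()
  if (!object@index %in% 1:3) msg <- c(msg, "index must be 1, 2 or 3")
  if (!object@context %in% c("unpaired-region", "hairpin-loop"))
    msg <- c(msg, "context must be 'unpaired-region' or 'hairpin-loop'")
  if (!grepl("^[ACGU]+$", object@motif))
    msg <- c(msg, "motif must be over the alphabet {A,C,G,U}")
  if (!nchar(object@motif) %in% 4:5)
    msg <- c(msg, "motif must be 4 or 5 bases long")
  if (object@mismatchFactor < 0 || object@mismatchFactor > 1 ||
      object@loopSizeFactor < 0 || object@loopSizeFactor > 1)
    msg <- c(msg, "penalty factors must lie in [0, 1]")
  if (object@maxMismatch < 0 || object@maxLoopDeviation < 0)
    msg <- c(msg, "tolerated maxima must be non-negative")
  if (object@context == "hairpin-loop" && object@targetLoopSize < nchar(object@motif))
    msg <- c(msg, "targetLoopSize must be at least the motif length")
  if (length(msg)) msg else TRUE
})

#' RNA folding backend
#'
#' A pluggable minimum-free-energy engine. `foldFun` takes a character vector
#' of RNA sequences and returns a `data.frame` with columns `structure`
#' (dot-bracket) and `energy` (kcal/mol, <= 0). Backends must be
#' deterministic: the same sequence always yields the same structure and
#' energy.
#'
#' @slot name backend identifier, e.g. `"toy"` or `"vienna"`.
#' @slot version backend version string, recorded in run metadata.
#' @slot foldFun the vectorized folding function.
#'
#' @seealso [toyFoldingBackend()], [viennaFoldingBackend()], [foldSequences()]
#' @export
setClass("FoldingBackend",
  representation(name = "character", version = "character", foldFun = "function")
)

#' Simulation parameters
#'
#' The full parameter set of a lattice run: grid geometry, neighborhoods,
#' claim of the empty site, diffusion intensity, mutation rates, the
#' cis-promiscuity penalty base, energy parameters, activity specifications,
#' the replicator length interval and the initializer settings.
#'
#' @slot width,height grid dimensions in sites; both even and at least
#'   \code{2 * (2 h + 1)}.
#' @slot h metabolic neighborhood radius (Chebyshev); the \eqn{(2h+1)^2}
#'   square centered on a replicator, focal site included.
#' @slot replicationRadius replication neighborhood radius (Chebyshev) around
#'   an empty site.
#' @slot claimEmpty \eqn{C_e}, the claim of an empty site to remain empty.
#' @slot diffusion \eqn{D}, Margolus sweeps per generation; fractional parts
#'   are applied as a Bernoulli extra sweep.
#' @slot pSub,pIns,pDel per-base mutation probabilities during replication.
#' @slot m cis-promiscuity penalty base (>= 1); a strand carrying
#'   \eqn{\sigma} sites has all activities divided by \eqn{m^{\sigma - 1}}.
#' @slot energy an [EnergyParams-class] object.
#' @slot specs list of three [ActivitySpec-class] objects.
#' @slot minLength,maxLength replicator-valid length interval (nt).
#' @slot occupancy initial fraction of occupied sites.
#' @slot activeFraction initial fraction of occupants that are catalytically
#'   active (drawn from the generator templates).
#' @slot backend the [FoldingBackend-class] used for all folding.
#'
#' @seealso [simParams()], [initPopulation()], [runSimulation()]
#' @export
setClass("SimParams",
  representation(
    width = "integer", height = "integer", h = "integer",
    replicationRadius = "integer", claimEmpty = "numeric",
    diffusion = "numeric", pSub = "numeric", pIns = "numeric",
    pDel = "numeric", m = "numeric", energy = "EnergyParams",
    specs = "list", minLength = "integer", maxLength = "integer",
    occupancy = "numeric", activeFraction = "numeric",
    backend = "FoldingBackend"
  )
)

setValidity("SimParams", function(object) {
  msg <- character()
  need <- 2L * (2L * object@h + 1L)
  if (object@width < need || object@height < need)
    msg <- c(msg, sprintf("grid must be at least %d x %d for h = %d", need, need, object@h))
  if (object@width %% 2L != 0L || object@height %% 2L != 0L)
    msg <- c(msg, "grid dimensions must be even (Margolus block partition)")
  for (p in c("pSub", "pIns", "pDel", "occupancy", "activeFraction")) {
    v <- slot(object, p)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must lie in [0, 1]", p))
  }
  if (object@claimEmpty < 0) msg <- c(msg, "claimEmpty must be >= 0")
  if (object@diffusion < 0) msg <- c(msg, "diffusion must be >= 0")
  if (object@m < 1) msg <- c(msg, "m must be >= 1")
  if (object@h < 0 || object@replicationRadius < 1)
    msg <- c(msg, "h must be >= 0 and replicationRadius >= 1")
  if (object@minLength < 1 || object@maxLength < object@minLength)
    msg <- c(msg, "length interval must satisfy 1 <= minLength <= maxLength")
  if (length(object@specs) &&
      !all(vapply(object@specs, is, logical(1), "ActivitySpec")))
    msg <- c(msg, "specs must be a list of ActivitySpec objects")
  if (length(msg)) msg else TRUE
})

#' Toroidal replicator lattice
#'
#' The simulation state: a toroidal grid of sites, each empty or holding one
#' RNA strand, together with the parameter set, the generation counter, the
#' Margolus partition parity and a folding cache shared across operations.
#'
#' The grid is stored as a `width x height` character matrix of sequences;
#' `""` marks an empty site. Strand phenotypes (structure, energy, folding
#' probability, degradation, replicability, catalytic activities) are derived
#' from the sequence on demand and memoized by sequence string.
#'
#' @slot grid character matrix of sequences, `""` for empty sites.
#' @slot generation generation counter.
#' @slot parity Margolus block-partition parity (alternates between sweeps).
#' @slot params the [SimParams-class] of the run.
#' @slot foldCache environment memoizing sequence -> (structure, energy).
#'
#' @seealso [initPopulation()], [stepGeneration()], [summarizeLattice()]
#' @export
setClass("ReplicatorLattice",
  representation(
    grid = "matrix", generation = "integer", parity = "integer",
    params = "SimParams", foldCache = "environment"
  )
)

setValidity("ReplicatorLattice", function(object) {
  msg <- character()
  if (!is.character(object@grid))
    msg <- c(msg, "grid must be a character matrix")
  if (!identical(dim(object@grid),
                 c(object@params@width, object@params@height)))
    msg <- c(msg, "grid dimensions must match params width x height")
  occ <- object@grid[object@grid != ""]
  if (length(occ) && !all(grepl("^[ACGU]+$", occ)))
    msg <- c(msg, "occupied sites must hold sequences over {A,C,G,U}")
  if (length(msg)) msg else TRUE
})

#' Error-threshold sweep scenario
#'
#' Configuration of an empirical error-threshold experiment: a grid of
#' effective mutation rates (each split among substitution, insertion and
#' deletion in fixed proportions), a number of replicate runs per rate, a
#' horizon, and the survival criterion. In the pre-adaptive scenario every
#' replicate first runs a burn-in at low mutation rates before the target
#' rate is imposed; in the non-adaptive scenario the target rate applies from
#' generation zero.
#'
#' @slot kind `"non-adaptive"` or `"pre-adaptive"`.
#' @slot rates effective mutation rates (sum of pSub, pIns, pDel) to sweep.
#' @slot proportions how an effective rate is partitioned among
#'   (substitution, insertion, deletion).
#' @slot replicates replicate runs per rate level.
#' @slot horizon generations per replicate after any burn-in.
#' @slot burnin burn-in length in generations (pre-adaptive only).
#' @slot burninRates c(pSub, pIns, pDel) during the burn-in.
#' @slot survivalMinOccupancy minimum final occupied fraction for survival.
#' @slot survivalWindow a surviving run must also show at least one
#'   replication event within this many final generations.
#' @slot params base [SimParams-class].
#'
#' @seealso [scenarioConfig()], [runScenario()], [estimateThreshold()]
#' @export
setClass("Scenario",
  representation(
    kind = "character", rates = "numeric", proportions = "numeric",
    replicates = "integer", horizon = "integer", burnin = "integer",
    burninRates = "numeric", survivalMinOccupancy = "numeric",
    survivalWindow = "integer", params = "SimParams"
  )
)

setValidity("Scenario", function(object) {
  msg <- character()
  if (!object@kind %in% c("non-adaptive", "pre-adaptive"))
    msg <- c(msg, "kind must be 'non-adaptive' or 'pre-adaptive'")
  if (is.unsorted(object@rates)) msg <- c(msg, "rates must be sorted increasing")
  if (any(object@rates < 0)) msg <- c(msg, "rates must be non-negative")
  if (object@replicates < 1) msg <- c(msg, "replicates must be >= 1")
  if (length(object@proportions) != 3 || any(object@proportions < 0))
    msg <- c(msg, "proportions must be 3 non-negative numbers")
  if (length(object@burninRates) != 3)
    msg <- c(msg, "burninRates must be c(pSub, pIns, pDel)")
  if (length(msg)) msg else TRUE
})

#' Result of an error-threshold sweep
#'
#' @slot table `data.frame` with one row per rate level: `rate`,
#'   `survivors`, `replicates`, `fraction`.
#' @slot outcomes logical matrix, rate levels x replicates.
#' @slot scenario the [Scenario-class] that produced the sweep.
#'
#' @seealso [runScenario()], [estimateThreshold()]
#' @export
setClass("SweepResult",
  representation(table = "data.frame", outcomes = "matrix", scenario = "Scenario")
)

# ---- show methods ---------------------------------------------------------

setMethod("show", "EnergyParams", function(object) {
  cat("EnergyParams: c =", object@c, " delta0 =", object@delta0,
      " delta1 =", object@delta1, " Emin =", object@Emin, "\n",
      "              g =", object@g, " l =", object@l, " b1 =", object@b1,
      " b2 =", object@b2, "\n")
})

setMethod("show", "ActivitySpec", function(object) {
  cat(sprintf("ActivitySpec E%d: motif %s in %s", object@index, object@motif,
              object@context))
  if (object@context == "hairpin-loop")
    cat(sprintf(" (target loop %d nt)", object@targetLoopSize))
  cat("\n")
})

setMethod("show", "FoldingBackend", function(object) {
  cat(sprintf("FoldingBackend '%s' (version %s)\n", object@name, object@version))
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf("SimParams: %d x %d torus, h = %d, replication radius = %d\n",
              object@width, object@height, object@h, object@replicationRadius))
  cat(sprintf("  C_e = %g, D = %g, m = %g, lengths [%d, %d]\n",
              object@claimEmpty, object@diffusion, object@m,
              object@minLength, object@maxLength))
  cat(sprintf("  mutation: pSub = %g, pIns = %g, pDel = %g\n",
              object@pSub, object@pIns, object@pDel))
  cat(sprintf("  init: occupancy = %g, active fraction = %g; backend '%s'\n",
              object@occupancy, object@activeFraction, object@backend@name))
})

setMethod("show", "ReplicatorLattice", function(object) {
  n <- sum(object@grid != "")
  cat(sprintf("ReplicatorLattice %d x %d at generation %d: %d occupied (%.1f%%)\n",
              nrow(object@grid), ncol(object@grid), object@generation, n,
              100 * n / length(object@grid)))
})

setMethod("show", "Scenario", function(object) {
  cat(sprintf("Scenario '%s': %d rate levels x %d replicates, horizon %d\n",
              object@kind, length(object@rates), object@replicates,
              object@horizon))
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult ('%s' scenario):\n", object@scenario@kind))
  print(object@table, row.names = FALSE)
})

# ---- accessors ------------------------------------------------------------

#' @describeIn ReplicatorLattice grid dimensions `c(width, height)`.
#' @param x a `ReplicatorLattice`.
#' @export
setMethod("dim", "ReplicatorLattice", function(x) dim(x@grid))

#' Accessors for lattice state
#'
#' `occupiedSequences` returns the sequences of all occupied sites,
#' `occupiedFraction` the fraction of occupied sites, `currentGeneration`
#' the generation counter and `simParams` the parameter set of a lattice.
#'
#' @param x a [ReplicatorLattice-class].
#' @return see individual descriptions.
#' @export
occupiedSequences <- function(x) {
  stopifnot(is(x, "ReplicatorLattice"))
  as.character(x@grid[x@grid != ""])
}

#' @rdname occupiedSequences
#' @export
occupiedFraction <- function(x) {
  stopifnot(is(x, "ReplicatorLattice"))
  sum(x@grid != "") / length(x@grid)
}

#' @rdname occupiedSequences
#' @export
currentGeneration <- function(x) {
  stopifnot(is(x, "ReplicatorLattice"))
  x@generation
}

#' @rdname occupiedSequences
#' @export
simParams <- function(x) {
  stopifnot(is(x, "ReplicatorLattice"))
  x@params
}
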