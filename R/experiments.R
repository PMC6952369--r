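#' Partition an effective mutation rate
#'
#' The effective mutation rate is the sum of the substitution, insertion
#' and deletion probabilities. A target effective rate is split among the
#' three event types in fixed proportions; the default 10:1:1 mirrors the
#' low initiation rates (0.005, 0.0005, 0.0005).
#'
#' @param effective effective mutation rate(s).
#' @param proportions relative weights of (substitution, insertion,
#'   deletion).
#' @return for a single rate, a named vector `c(pSub, pIns, pDel)`; for
#'   several, a matrix with one row per rate.
#' @examples
#' mutationRateSplit(0.006)  # the burn-in rates
#' @export
mutationRateSplit <- function(effective, proportions = c(10, 1, 1)) {
  w <- proportions / sum(proportions)
  out <- outer(effective, w)
  colnames(out) <- c("pSub", "pIns", "pDel")
  if (length(effective) == 1L) out[1, ] else out
}

#' Configure an error-threshold scenario
#'
#' @param kind `"non-adaptive"` (target mutation rate from generation 0) or
#'   `"pre-adaptive"` (burn-in at low rates, then the target rate).
#' @param rates effective mutation rates to sweep (sorted increasing).
#' @param replicates replicate runs per rate level.
#' @param horizon generations per replicate (after any burn-in).
#' @param burnin burn-in generations for the pre-adaptive scenario.
#' @param burninRates `c(pSub, pIns, pDel)` during burn-in.
#' @param proportions partition of an effective rate, see
#'   [mutationRateSplit()].
#' @param survivalMinOccupancy a replicate survives if its final occupied
#'   fraction is at least this value ...
#' @param survivalWindow ... and at least one replication event occurred in
#'   this many final generations.
#' @param params base [SimParams-class] (mutation-rate slots are
#'   overridden per level).
#' @return a [Scenario-class].
#' @export
scenarioConfig <- function(kind = c("non-adaptive", "pre-adaptive"),
                           rates, replicates = 5, horizon = 1000,
                           burnin = 1000,
                           burninRates = c(0.005, 5e-4, 5e-4),
                           proportions = c(10, 1, 1),
                           survivalMinOccupancy = 0.01,
                           survivalWindow = 100,
                           params = simParams()) {
  kind <- match.arg(kind)
  new("Scenario", kind = kind, rates = as.numeric(rates),
      proportions = as.numeric(proportions),
      replicates = as.integer(replicates), horizon = as.integer(horizon),
      burnin = as.integer(burnin), burninRates = as.numeric(burninRates),
      survivalMinOccupancy = survivalMinOccupancy,
      survivalWindow = as.integer(survivalWindow), params = params)
}

.with_rates <- function(params, rates) {
  params@pSub <- unname(rates[1])
  params@pIns <- unname(rates[2])
  params@pDel <- unname(rates[3])
  params
}

.survived <- function(run, minOcc, window) {
  occ <- occupiedFraction(run$lattice)
  ev <- run$events
  recent <- ev[ev$t > max(ev$t) - window, , drop = FALSE]
  occ >= minOcc && sum(recent$replications) >= 1
}

#' Run an error-threshold sweep
#'
#' For each effective mutation rate, runs independent replicate simulations
#' and records whether each survives the horizon. In the non-adaptive
#' scenario the target rates apply from generation 0. In the pre-adaptive
#' scenario every replicate first runs a burn-in at the low rates (so the
#' community has converged towards evolved, compactly folded replicators)
#' and only then is the target rate imposed for the horizon. Survival
#' requires a minimum final occupancy and at least one replication event in
#' the final window. Per-replicate seeds are derived up front from the
#' current RNG state, so the sweep is reproducible from one `set.seed()`.
#'
#' @param scenario a [Scenario-class].
#' @param verbose log per-replicate progress to `stderr`.
#' @return a [SweepResult-class].
#' @seealso [estimateThreshold()]
#' @export
runScenario <- function(scenario, verbose = FALSE) {
  stopifnot(is(scenario, "Scenario"))
  validObject(scenario)
  nr <- length(scenario@rates)
  outcomes <- matrix(NA, nr, scenario@replicates)
  seeds <- matrix(sample.int(.Machine$integer.max, nr * scenario@replicates),
                  nr, scenario@replicates)
  for (i in seq_len(nr)) {
    target <- mutationRateSplit(scenario@rates[i], scenario@proportions)
    for (r in seq_len(scenario@replicates)) {
      set.seed(seeds[i, r])
      if (scenario@kind == "pre-adaptive") {
        p0 <- .with_rates(scenario@params, scenario@burninRates)
        lat <- initPopulation(p0)
        if (scenario@burnin > 0)
          lat <- runSimulation(lat, scenario@burnin, recordEvery = 0L)$lattice
        lat@params <- .with_rates(lat@params, target)
      } else {
        lat <- initPopulation(.with_rates(scenario@params, target))
      }
      run <- runSimulation(lat, scenario@horizon, recordEvery = 0L)
      outcomes[i, r] <- .survived(run, scenario@survivalMinOccupancy,
                                  scenario@survivalWindow)
      if (verbose)
        message(sprintf("[sweep] rate %g replicate %d: %s", scenario@rates[i],
                        r, if (outcomes[i, r]) "survived" else "collapsed"))
    }
  }
  tab <- data.frame(rate = scenario@rates, survivors = rowSums(outcomes),
                    replicates = scenario@replicates,
                    fraction = rowMeans(outcomes))
  new("SweepResult", table = tab, outcomes = outcomes, scenario = scenario)
}

#' Estimate the empirical error threshold
#'
#' The threshold is read off the sweep as the largest rate on the grid
#' whose surviving fraction is at least `level` (default 1/2); at
#' `level = 0` it is the largest rate with any survivor. If no rate
#' qualifies, `-Inf` is returned as the "below grid minimum" marker. The
#' estimate is non-increasing in `level`.
#'
#' @param res a [SweepResult-class], or its `table` data.frame.
#' @param level required surviving fraction.
#' @return the estimated effective mutation rate, or `-Inf`.
#' @examples
#' tab <- data.frame(rate = c(0.01, 0.02, 0.03, 0.04),
#'                   fraction = c(1, 1, 0.4, 0))
#' estimateThreshold(tab)        # 0.02
#' @export
estimateThreshold <- function(res, level = 0.5) {
  tab <- if (is(res, "SweepResult")) res@table else res
  stopifnot(is.data.frame(tab), !is.unsorted(tab$rate))
  ok <- if (level > 0) tab$fraction >= level else tab$fraction > 0
  if (!any(ok)) return(-Inf)
  max(tab$rate[ok])
}
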