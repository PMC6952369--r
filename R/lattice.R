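#' Construct simulation parameters
#'
#' Defaults follow the model's reference setting: a 300 x 300 torus, 3 x 3
#' metabolic neighborhood (h = 1, focal site included), 8-cell replication
#' neighborhood, diffusion intensity D = 1, length interval 15..75 nt,
#' initial occupancy 0.8 with half of the occupants catalytically active,
#' and the low burn-in mutation rates (pSub = 0.005, pIns = pDel = 0.0005).
#' Tests and examples use smaller grids.
#'
#' @param width,height grid dimensions (even).
#' @param h metabolic neighborhood radius (Chebyshev).
#' @param replicationRadius replication neighborhood radius (Chebyshev).
#' @param claimEmpty \eqn{C_e}, claim of an empty site to remain empty.
#' @param diffusion \eqn{D}, Margolus sweeps per generation.
#' @param pSub,pIns,pDel per-base mutation probabilities.
#' @param m cis-promiscuity penalty base.
#' @param energy an [EnergyParams-class].
#' @param specs list of [ActivitySpec-class] objects.
#' @param minLength,maxLength replicator-valid length interval (nt).
#' @param occupancy initial occupied fraction.
#' @param activeFraction initial catalytically active fraction of occupants.
#' @param backend a [FoldingBackend-class].
#' @return a [SimParams-class].
#' @examples
#' simParams(width = 20, height = 20)
#' @export
simParams <- function(width = 300, height = 300, h = 1, replicationRadius = 1,
                      claimEmpty = 2, diffusion = 1, pSub = 0.005,
                      pIns = 5e-4, pDel = 5e-4, m = 2,
                      energy = energyParams(), specs = defaultActivitySpecs(),
                      minLength = 15, maxLength = 75, occupancy = 0.8,
                      activeFraction = 0.5, backend = toyFoldingBackend()) {
  new("SimParams", width = as.integer(width), height = as.integer(height),
      h = as.integer(h), replicationRadius = as.integer(replicationRadius),
      claimEmpty = claimEmpty, diffusion = diffusion, pSub = pSub,
      pIns = pIns, pDel = pDel, m = m, energy = energy, specs = specs,
      minLength = as.integer(minLength), maxLength = as.integer(maxLength),
      occupancy = occupancy, activeFraction = activeFraction,
      backend = backend)
}

.simpar_as_list <- function(p) {
  list(Ce = p@claimEmpty, D = p@diffusion, pSub = p@pSub, pIns = p@pIns,
       pDel = p@pDel, m = p@m, h = p@h, rr = p@replicationRadius,
       minLength = p@minLength, maxLength = p@maxLength)
}

# Candidate stem pairs used when constructing generator templates; each is
# verified against the configured backend before use.
.template_stems <- list(
  c("GGGGG", "CCCCC"), c("GCGCG", "CGCGC"), c("GGCGG", "CCGCC"),
  c("CGGGC", "GCCCG"), c("GGGCG", "CGCCC")
)

#' Generator templates for the initial population
#'
#' Constructs, for each activity specification, a sequence that the
#' configured folding backend folds into a structure carrying exactly that
#' one catalytic site at full specific activity (alpha = 1). Hairpin
#' activities get a stem-loop with the motif inside a loop of the target
#' size; the unpaired-region activity gets its motif on an unpaired tail
#' next to a stable hairpin. Every candidate is verified by folding and site
#' detection, so the construction holds for any backend; an error is raised
#' if no candidate satisfies a user-supplied specification.
#'
#' @param params a [SimParams-class].
#' @return character vector of one template per activity, named `E1`..`E3`.
#' @export
generatorTemplates <- function(params = simParams()) {
  stopifnot(is(params, "SimParams"))
  out <- character(length(params@specs))
  names(out) <- paste0("E", vapply(params@specs, slot, 1L, "index"))
  for (k in seq_along(params@specs)) {
    sp <- params@specs[[k]]
    cands <- character()
    for (stems in .template_stems) {
      if (sp@context == "hairpin-loop") {
        pad <- sp@targetLoopSize - nchar(sp@motif)
        loops <- unique(c(
          paste0(sp@motif, strrep("A", pad)),
          paste0(strrep("A", pad), sp@motif),
          paste0(sp@motif, strrep("C", pad))
        ))
        for (lp in loops) {
          hp <- paste0(stems[1], lp, stems[2])
          cands <- c(cands, hp, paste0("AA", hp), paste0(hp, "AA"))
        }
      } else {
        hp <- paste0(stems[1], "AAAA", stems[2])
        cands <- c(cands,
                   paste0(hp, "AA", sp@motif),
                   paste0(sp@motif, "AA", hp),
                   paste0(hp, "A", sp@motif, "A"))
      }
    }
    cands <- cands[nchar(cands) >= params@minLength &
                     nchar(cands) <= params@maxLength]
    found <- NA_character_
    for (cand in cands) {
      ann <- annotateStrands(cand, params)
      ai <- ann[[paste0("a", sp@index)]]
      if (ann$sigma == 1L && ai > 0 &&
          isTRUE(all.equal(ai, ann$pfold, tolerance = 1e-12))) {
        found <- cand
        break
      }
    }
    if (is.na(found))
      stop(sprintf(paste0("could not construct a generator template for ",
                          "activity %d (motif '%s', context '%s') under the ",
                          "'%s' backend"),
                   sp@index, sp@motif, sp@context, params@backend@name),
           call. = FALSE)
    out[k] <- found
  }
  out
}

.random_sequences <- function(n, minL, maxL) {
  lens <- sample(seq.int(minL, maxL), n, replace = TRUE)
  vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = ""),
    character(1))
}

#' Initialize a replicator population
#'
#' Spatially random ("layered") allocation: each site is independently
#' occupied with probability `occupancy`; each occupant is catalytically
#' active with probability `activeFraction`. Active occupants are drawn
#' uniformly from the three generator templates (with at least one carrier
#' of every activity type whenever three or more actives are drawn);
#' inactive occupants are uniform random sequences of length 15..75 nt,
#' resampled until they carry no catalytic site, so that the realized
#' active fraction is `occupancy * activeFraction` in expectation. Fully
#' reproducible from the R random seed.
#'
#' @param params a [SimParams-class].
#' @return a [ReplicatorLattice-class] at generation 0.
#' @examples
#' set.seed(1)
#' lat <- initPopulation(simParams(width = 20, height = 20))
#' occupiedFraction(lat)
#' @export
initPopulation <- function(params = simParams()) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  W <- params@width; H <- params@height
  n <- W * H
  cache <- new.env(parent = emptyenv())
  grid <- matrix("", nrow = W, ncol = H)
  occupied <- which(stats::runif(n) < params@occupancy)
  if (length(occupied)) {
    active <- stats::runif(length(occupied)) < params@activeFraction
    nact <- sum(active)
    if (nact > 0) {
      templates <- generatorTemplates(params)
      idx <- sample.int(length(templates), nact, replace = TRUE)
      if (nact >= length(templates)) {
        missing <- setdiff(seq_along(templates), unique(idx))
        if (length(missing))
          idx[sample.int(nact, length(missing))] <- missing
      }
      grid[occupied[active]] <- templates[idx]
    }
    ninact <- sum(!active)
    if (ninact > 0) {
      kept <- character(0)
      while (length(kept) < ninact) {
        batch <- .random_sequences(max(64L, ninact - length(kept)),
                                   params@minLength, params@maxLength)
        ann <- annotateStrands(batch, params, cache)
        kept <- c(kept, batch[ann$sigma == 0L])
      }
      grid[occupied[!active]] <- kept[seq_len(ninact)]
    }
  }
  lat <- new("ReplicatorLattice", grid = grid, generation = 0L, parity = 0L,
             params = params, foldCache = cache)
  # warm the cache for all resident sequences
  invisible(annotateStrands(unique(occupiedSequences(lat)), params, cache))
  lat
}

.activity_fields <- function(lat) {
  seqs <- occupiedSequences(lat)
  A <- array(0, dim = c(nrow(lat@grid), ncol(lat@grid), 3))
  if (!length(seqs)) return(A)
  uq <- unique(seqs)
  ann <- annotateStrands(uq, lat@params, lat@foldCache)
  idx <- match(lat@grid, uq)      # NA for empty / unmatched
  occ <- which(!is.na(idx))
  for (k in 1:3) {
    Ak <- A[, , k]
    Ak[occ] <- ann[[paste0("a", k)]][idx[occ]]
    A[, , k] <- Ak
  }
  A
}

.wrap <- function(i, n) ((i - 1) %% n) + 1L

#' Metabolic activity of a site
#'
#' The geometric mean of the three per-activity sums over the Chebyshev-h
#' metabolic neighborhood centered on (`x`, `y`), focal site included:
#' \eqn{M = [\prod_i \sum_{j \in \Delta_h} a_{i,j}]^{1/3}}. It is zero
#' whenever any essential activity is absent from the neighborhood
#' (metabolic incompleteness vetoes replication).
#'
#' @param lat a [ReplicatorLattice-class].
#' @param x,y 1-based site coordinates.
#' @param fields optional precomputed activity array (internal use).
#' @return the metabolic activity \eqn{M \ge 0}.
#' @export
metabolicActivity <- function(lat, x, y, fields = NULL) {
  stopifnot(is(lat, "ReplicatorLattice"))
  if (is.null(fields)) fields <- .activity_fields(lat)
  W <- nrow(lat@grid); H <- ncol(lat@grid); h <- lat@params@h
  xs <- .wrap(x + (-h:h), W)
  ys <- .wrap(y + (-h:h), H)
  s <- vapply(1:3, function(k) sum(fields[xs, ys, k]), numeric(1))
  if (any(s <= 0)) return(0)
  prod(s)^(1 / 3)
}

#' Replication claims on an empty site
#'
#' For an empty focal site, every occupied site in its replication
#' neighborhood claims it with weight \eqn{C_f = M_f R_f} (metabolic
#' activity times replicability, both evaluated for the claimant), and the
#' empty site claims itself with \eqn{C_e}. Claim weights are normalized to
#' the probability vector \eqn{P_f = C_f / (C_e + \sum_j C_j)}; claimants
#' with incomplete metabolic neighborhoods contribute nothing.
#'
#' @param lat a [ReplicatorLattice-class].
#' @param x,y coordinates of an empty site.
#' @return a list with `claimants` (`data.frame`: `x`, `y`, `sequence`,
#'   `claim`, `probability`) and `stayEmpty` (probability that the site
#'   remains empty). All probabilities sum to 1.
#' @export
replicationClaims <- function(lat, x, y) {
  stopifnot(is(lat, "ReplicatorLattice"))
  if (lat@grid[x, y] != "")
    stop(sprintf("site (%d, %d) is not empty", x, y), call. = FALSE)
  fields <- .activity_fields(lat)
  p <- lat@params
  W <- nrow(lat@grid); H <- ncol(lat@grid); rr <- p@replicationRadius
  ann_cache <- annotateStrands(unique(occupiedSequences(lat)), p, lat@foldCache)
  cx <- integer(0); cy <- integer(0); cseq <- character(0); cl <- numeric(0)
  for (dy in -rr:rr) for (dx in -rr:rr) {
    if (dx == 0 && dy == 0) next
    nx <- .wrap(x + dx, W); ny <- .wrap(y + dy, H)
    s <- lat@grid[nx, ny]
    if (s == "") next
    M <- metabolicActivity(lat, nx, ny, fields)
    if (M <= 0) next
    R <- ann_cache$R[match(s, ann_cache$sequence)]
    C <- M * R
    if (C <= 0) next
    cx <- c(cx, nx); cy <- c(cy, ny); cseq <- c(cseq, s); cl <- c(cl, C)
  }
  tot <- p@claimEmpty + sum(cl)
  list(
    claimants = data.frame(x = cx, y = cy, sequence = cseq, claim = cl,
                           probability = if (length(cl)) cl / tot else numeric(0)),
    stayEmpty = p@claimEmpty / tot
  )
}

#' Template-directed replication with mutation
#'
#' Synthesizes the reverse complement of the template base by base. At each
#' template position a single, mutually exclusive categorical draw selects
#' faithful incorporation, substitution (uniform over the three other
#' bases, probability `pSub`), deletion (the base is skipped, `pDel`) or
#' insertion (an extra uniform base precedes the faithful one, `pIns`); one
#' trailing insertion opportunity follows the final base. With all rates
#' zero the product is the exact reverse complement. A product outside the
#' replicator-valid length interval is a failed replication.
#'
#' @param template RNA sequence to copy.
#' @param params a [SimParams-class] (mutation rates and length bounds).
#' @return the daughter sequence, or `NA_character_` on length-bound
#'   failure.
#' @export
replicateWithMutation <- function(template, params = simParams()) {
  .check_rna(template)
  p <- params
  bases <- c("A", "C", "G", "U")
  tmpl <- rev(strsplit(template, "")[[1]])
  comp <- c(A = "U", U = "A", G = "C", C = "G")[tmpl]
  out <- character(0)
  u <- stats::runif(length(tmpl))
  for (i in seq_along(tmpl)) {
    if (u[i] < p@pDel) {
      next
    } else if (u[i] < p@pDel + p@pSub) {
      out <- c(out, sample(setdiff(bases, comp[i]), 1))
    } else if (u[i] < p@pDel + p@pSub + p@pIns) {
      out <- c(out, sample(bases, 1), comp[i])
    } else {
      out <- c(out, comp[i])
    }
  }
  if (stats::runif(1) < p@pIns) out <- c(out, sample(bases, 1))
  if (length(out) < p@minLength || length(out) > p@maxLength)
    return(NA_character_)
  paste(out, collapse = "")
}

#' Toffoli-Margolus diffusion
#'
#' Each sweep partitions the torus into 2 x 2 blocks (the partition offset
#' alternates between (0,0) and (1,1) on successive sweeps) and rotates
#' every block 90 degrees clockwise or counter-clockwise with probability
#' 1/2 each. `floor(D)` sweeps are applied, plus one more with probability
#' `frac(D)`. Occupants are permuted, never created or destroyed, so the
#' occupant multiset is exactly conserved.
#'
#' @param lat a [ReplicatorLattice-class] (even dimensions).
#' @param D diffusion intensity; defaults to the lattice's parameter.
#' @return the diffused lattice.
#' @export
diffuse <- function(lat, D = lat@params@diffusion) {
  stopifnot(is(lat, "ReplicatorLattice"))
  r <- cpp_diffuse(seq_along(lat@grid), nrow(lat@grid), ncol(lat@grid),
                   D, lat@parity)
  lat@grid <- matrix(lat@grid[r$grid], nrow = nrow(lat@grid))
  lat@parity <- as.integer(r$parity)
  lat
}

.run_engine <- function(lat, generations, recordEvery) {
  p <- lat@params
  keys <- ls(envir = lat@foldCache, all.names = TRUE, sorted = FALSE)
  if (length(keys)) {
    hits <- mget(keys, envir = lat@foldCache)
    cstr <- vapply(hits, function(h) h$structure, character(1))
    cen <- vapply(hits, function(h) h$energy, numeric(1))
  } else {
    cstr <- character(0); cen <- numeric(0)
  }
  useToy <- p@backend@name == "toy"
  foldFun <- function(seq) {
    r <- p@backend@foldFun(seq)
    list(structure = r$structure[1], energy = r$energy[1])
  }
  res <- cpp_run(as.vector(lat@grid), nrow(lat@grid), ncol(lat@grid),
                 .energy_as_list(p@energy), .simpar_as_list(p),
                 .specs_as_list(p@specs), keys, cstr, cen,
                 as.integer(generations), as.integer(recordEvery),
                 lat@generation, lat@parity, useToy, foldFun)
  newKeys <- as.character(res$cacheSeqs)
  fresh <- !(newKeys %in% keys)
  if (any(fresh)) {
    st <- as.character(res$cacheStructs); en <- as.numeric(res$cacheEnergies)
    for (i in which(fresh))
      assign(newKeys[i], list(structure = st[i], energy = en[i]),
             envir = lat@foldCache)
  }
  lat@grid <- matrix(as.character(res$grid), nrow = nrow(lat@grid))
  lat@generation <- as.integer(res$generation)
  lat@parity <- as.integer(res$parity)
  list(lattice = lat, trajectory = res$trajectory, events = res$events)
}

#' Advance the lattice by one generation
#'
#' A generation consists of `width * height` elementary updates, each on an
#' independently, uniformly chosen site ("each site once on average"). An
#' occupied site degrades with its strand's \eqn{p_{deg}} and is emptied; an
#' empty site draws from its replication-claim distribution, and a winning
#' claimant's strand is copied (reverse complement with mutation) into the
#' site, provided the product stays within the length bounds. After all
#' updates, Margolus diffusion is applied and the generation counter
#' increments.
#'
#' @param lat a [ReplicatorLattice-class].
#' @return a list with `lattice` (advanced state) and `events` (one-row
#'   `data.frame`: `updates`, `degradations`, `replications`,
#'   `failedReplications`, and mutation counts by type).
#' @export
stepGeneration <- function(lat) {
  r <- .run_engine(lat, 1L, 0L)
  list(lattice = r$lattice, events = r$events)
}

#' Run a simulation
#'
#' Executes `generations` generations of the full dynamics, recording a
#' trajectory summary every `recordEvery` generations (plus the initial and
#' final state) and per-generation event counts. Identical parameters and
#' random seed reproduce the run exactly.
#'
#' @param lat a [ReplicatorLattice-class], e.g. from [initPopulation()].
#' @param generations number of generations to run.
#' @param recordEvery trajectory recording cadence in generations.
#' @return a list with `lattice` (final state), `trajectory` (`data.frame`
#'   of per-record class frequencies, mean length/replicability/energy/
#'   activities and population size) and `events` (per-generation counts).
#' @examples
#' set.seed(7)
#' lat <- initPopulation(simParams(width = 16, height = 16))
#' out <- runSimulation(lat, generations = 5, recordEvery = 1)
#' tail(out$trajectory, 2)
#' @export
runSimulation <- function(lat, generations, recordEvery = max(1L, generations %/% 100L)) {
  stopifnot(is(lat, "ReplicatorLattice"), generations >= 1)
  .run_engine(lat, generations, recordEvery)
}
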