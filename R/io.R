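#' Write simulation parameters to a YAML run configuration
#'
#' The configuration round-trips losslessly: `readRunConfig(writeRunConfig(p))`
#' reconstructs an identical parameter set. The folding backend is stored by
#' name and re-resolved on load.
#'
#' @param params a [SimParams-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readRunConfig()]
#' @export
writeRunConfig <- function(params, path) {
  stopifnot(is(params, "SimParams"))
  e <- params@energy
  cfg <- list(
    grid = list(width = params@width, height = params@height),
    neighborhoods = list(metabolicRadius = params@h,
                         replicationRadius = params@replicationRadius),
    dynamics = list(claimEmpty = params@claimEmpty,
                    diffusion = params@diffusion, m = params@m),
    mutation = list(pSub = params@pSub, pIns = params@pIns, pDel = params@pDel),
    lengths = list(min = params@minLength, max = params@maxLength),
    init = list(occupancy = params@occupancy,
                activeFraction = params@activeFraction),
    energy = list(c = e@c, delta0 = e@delta0, delta1 = e@delta1,
                  Emin = e@Emin, g = e@g, l = e@l, b1 = e@b1, b2 = e@b2),
    backend = params@backend@name,
    activities = lapply(params@specs, function(s) list(
      index = s@index, context = s@context, motif = s@motif,
      targetLoopSize = s@targetLoopSize, mismatchFactor = s@mismatchFactor,
      maxMismatch = s@maxMismatch, loopSizeFactor = s@loopSizeFactor,
      maxLoopDeviation = s@maxLoopDeviation))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

.cfg_get <- function(cfg, ...) {
  keys <- c(...)
  node <- cfg
  for (k in keys) {
    if (is.null(node[[k]]))
      stop(sprintf("run configuration is missing '%s'", paste(keys, collapse = "/")),
           call. = FALSE)
    node <- node[[k]]
  }
  node
}

#' Read a YAML run configuration
#'
#' Strictly validates the configuration (every S4 validity invariant is
#' checked) and resolves the folding backend by name; validation failures
#' name the offending parameter.
#'
#' @param path path to a YAML file written by [writeRunConfig()] (or by
#'   hand with the same layout).
#' @return a [SimParams-class].
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  energy <- do.call(energyParams, .cfg_get(cfg, "energy"))
  specs <- lapply(.cfg_get(cfg, "activities"), function(s)
    activitySpec(s$index, s$context, s$motif, s$targetLoopSize,
                 s$mismatchFactor, s$maxMismatch, s$loopSizeFactor,
                 s$maxLoopDeviation))
  simParams(
    width = .cfg_get(cfg, "grid", "width"),
    height = .cfg_get(cfg, "grid", "height"),
    h = .cfg_get(cfg, "neighborhoods", "metabolicRadius"),
    replicationRadius = .cfg_get(cfg, "neighborhoods", "replicationRadius"),
    claimEmpty = .cfg_get(cfg, "dynamics", "claimEmpty"),
    diffusion = .cfg_get(cfg, "dynamics", "diffusion"),
    m = .cfg_get(cfg, "dynamics", "m"),
    pSub = .cfg_get(cfg, "mutation", "pSub"),
    pIns = .cfg_get(cfg, "mutation", "pIns"),
    pDel = .cfg_get(cfg, "mutation", "pDel"),
    minLength = .cfg_get(cfg, "lengths", "min"),
    maxLength = .cfg_get(cfg, "lengths", "max"),
    occupancy = .cfg_get(cfg, "init", "occupancy"),
    activeFraction = .cfg_get(cfg, "init", "activeFraction"),
    energy = energy, specs = specs,
    backend = foldingBackend(.cfg_get(cfg, "backend"))
  )
}

#' Write a lattice snapshot to FASTA
#'
#' One record per occupied site. The record id is `x_y_t` (1-based site
#' coordinates and the generation counter); the description carries the
#' strand phenotype as `key=value` pairs (`E`, `pfold`, `a1`..`a3`,
#' `class`).
#'
#' @param lat a [ReplicatorLattice-class].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @seealso [readSnapshot()]
#' @export
writeSnapshot <- function(lat, path) {
  stopifnot(is(lat, "ReplicatorLattice"))
  occ <- which(lat@grid != "", arr.ind = TRUE)
  seqs <- lat@grid[lat@grid != ""]
  if (length(seqs)) {
    ann <- annotateStrands(unique(seqs), lat@params, lat@foldCache)
    ann <- ann[match(seqs, ann$sequence), ]
    ids <- sprintf("%d_%d_%d E=%.4f pfold=%.6f a1=%.6f a2=%.6f a3=%.6f class=%s",
                   occ[, 1], occ[, 2], lat@generation, ann$energy, ann$pfold,
                   ann$a1, ann$a2, ann$a3, ann$class)
    set <- Biostrings::RNAStringSet(seqs)
    names(set) <- ids
  } else {
    set <- Biostrings::RNAStringSet()
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a lattice snapshot from FASTA
#'
#' Reconstructs a [ReplicatorLattice-class] from a snapshot written by
#' [writeSnapshot()]. Site coordinates and the generation counter are
#' parsed from the record ids; the grid geometry comes from `params`.
#'
#' @param path FASTA file path.
#' @param params the [SimParams-class] of the run.
#' @return a [ReplicatorLattice-class].
#' @export
readSnapshot <- function(path, params) {
  stopifnot(is(params, "SimParams"))
  set <- Biostrings::readRNAStringSet(path)
  grid <- matrix("", nrow = params@width, ncol = params@height)
  gen <- 0L
  if (length(set)) {
    ids <- sub("\\s.*$", "", names(set))
    parts <- strsplit(ids, "_", fixed = TRUE)
    bad <- lengths(parts) != 3L
    if (any(bad))
      stop(sprintf("malformed snapshot record id '%s' (expected x_y_t)",
                   ids[which(bad)[1]]), call. = FALSE)
    x <- as.integer(vapply(parts, `[`, character(1), 1L))
    y <- as.integer(vapply(parts, `[`, character(1), 2L))
    gen <- as.integer(parts[[1]][3])
    if (any(x < 1 | x > params@width | y < 1 | y > params@height))
      stop("snapshot coordinates fall outside the configured grid", call. = FALSE)
    grid[cbind(x, y)] <- as.character(set)
  }
  new("ReplicatorLattice", grid = grid, generation = gen, parity = 0L,
      params = params, foldCache = new.env(parent = emptyenv()))
}

#' Write a trajectory table to TSV
#'
#' @param trajectory a trajectory or event `data.frame` from
#'   [runSimulation()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(trajectory, path) {
  utils::write.table(trajectory, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Write run metadata as JSON
#'
#' Records everything needed to reproduce a run: the master seed, the
#' folding backend name and version, grid geometry, generation counter and
#' the package version.
#'
#' @param lat a [ReplicatorLattice-class].
#' @param path output JSON path.
#' @param seed the master seed of the run (if known).
#' @return `path`, invisibly.
#' @export
writeRunMetadata <- function(lat, path, seed = NA_integer_) {
  stopifnot(is(lat, "ReplicatorLattice"))
  meta <- list(
    package = as.character(utils::packageVersion("mcrs")),
    seed = seed,
    backend = list(name = lat@params@backend@name,
                   version = lat@params@backend@version),
    grid = list(width = nrow(lat@grid), height = ncol(lat@grid)),
    generation = lat@generation,
    occupied = sum(lat@grid != ""),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Checkpoint and restore a full lattice state
#'
#' A checkpoint is a directory of plain-text files: the run configuration
#' (YAML), the grid snapshot (FASTA), and a state file (JSON) holding the
#' generation counter, the Margolus parity and the complete R RNG state, so
#' a restored run continues the exact random sequence of the original.
#'
#' @param lat a [ReplicatorLattice-class].
#' @param dir checkpoint directory (created if needed).
#' @return `dir` (for `writeCheckpoint`) or the restored
#'   [ReplicatorLattice-class] (for `readCheckpoint`), invisibly/visibly.
#' @export
writeCheckpoint <- function(lat, dir) {
  stopifnot(is(lat, "ReplicatorLattice"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeRunConfig(lat@params, file.path(dir, "config.yaml"))
  writeSnapshot(lat, file.path(dir, "grid.fasta"))
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  jsonlite::write_json(
    list(generation = lat@generation, parity = lat@parity, rngState = rng),
    file.path(dir, "state.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(dir) {
  params <- readRunConfig(file.path(dir, "config.yaml"))
  lat <- readSnapshot(file.path(dir, "grid.fasta"), params)
  st <- jsonlite::read_json(file.path(dir, "state.json"))
  lat@generation <- as.integer(st$generation)
  lat@parity <- as.integer(st$parity)
  if (!is.null(st$rngState))
    assign(".Random.seed", as.integer(unlist(st$rngState)), envir = globalenv())
  lat
}
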