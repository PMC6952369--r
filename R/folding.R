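#' Construct energy parameters
#'
#' Defaults: `c = 0.3` and `Emin = -25` kcal/mol (a strand with zero free
#' energy is folded with probability 1/2; one at the empirical energy minimum
#' is folded almost certainly). The remaining values place the baseline
#' system in the persistent regime; see the methods vignette for how they
#' were chosen.
#'
#' @param c logistic steepness, 1/(kcal/mol).
#' @param delta0 baseline degradation probability per generation.
#' @param delta1 free-energy proportionality factor of degradation.
#' @param Emin empirical lower free-energy bound (kcal/mol).
#' @param g replicability scale.
#' @param l residual replicability of a fully folded strand.
#' @param b1 length-independent replication-time component.
#' @param b2 per-nucleotide replication-time component ("length penalty").
#' @return an [EnergyParams-class] object.
#' @examples
#' energyParams()
#' energyParams(b2 = 0.005)
#' @export
energyParams <- function(c = 0.3, delta0 = 0.02, delta1 = 0.014, Emin = -25,
                         g = 10, l = 0.3, b1 = 1, b2 = 0.01) {
  new("EnergyParams", c = c, delta0 = delta0, delta1 = delta1, Emin = Emin,
      g = g, l = l, b1 = b1, b2 = b2)
}

.check_rna <- function(x, what = "sequence") {
  bad <- !grepl("^[ACGU]+$", x)
  if (any(bad))
    stop(sprintf("invalid %s (alphabet must be {A,C,G,U}): '%s'",
                 what, x[which(bad)[1]]), call. = FALSE)
  invisible(x)
}

#' Folding probability from free energy
#'
#' The Boltzmann two-state form \eqn{p_{fold} = e^{-cE} / (1 + e^{-cE})}:
#' strictly decreasing in \eqn{E} with range (0, 1). At \eqn{E = 0} and
#' \eqn{c = 0.3} a strand is folded with probability exactly 1/2.
#'
#' @param E Gibbs free energy of the MFE structure, kcal/mol (vectorized).
#' @param c logistic steepness, > 0.
#' @return folding probabilities in (0, 1).
#' @examples
#' foldingProbability(0)        # 0.5
#' foldingProbability(-25)      # ~0.99945
#' @export
foldingProbability <- function(E, c = 0.3) {
  if (c <= 0) stop("c must be > 0", call. = FALSE)
  1 / (1 + exp(c * E))
}

#' Degradation probability from free energy
#'
#' Affine in the free energy: \eqn{p_{deg} = \delta_0 - \delta_1 E / E_{min}},
#' so a strand with \eqn{E = 0} degrades with probability \eqn{\delta_0} and
#' one at the empirical bound \eqn{E_{min}} with probability
#' \eqn{\delta_0 - \delta_1}. Energies outside \eqn{[E_{min}, 0]} are clamped
#' to the interval (the bound is empirical, not hard), keeping
#' \eqn{p_{deg} \in [\delta_0 - \delta_1, \delta_0]}.
#'
#' @param E free energies, kcal/mol (vectorized).
#' @param params an [EnergyParams-class] object.
#' @return per-generation degradation probabilities.
#' @export
degradationProbability <- function(E, params = energyParams()) {
  stopifnot(is(params, "EnergyParams"))
  validObject(params)
  E <- pmin(pmax(E, params@Emin), 0)
  params@delta0 - params@delta1 * E / params@Emin
}

#' Replicability of a strand
#'
#' \eqn{R = g (l + (1 - p_{fold})) / (b_1 + b_2 L)}: only the unfolded state
#' can serve as a template, so replicability decreases with folding
#' probability, and copying time grows with length, so it also decreases
#' with \eqn{L}.
#'
#' @param pfold folding probabilities (vectorized).
#' @param length strand lengths in nt (vectorized, recycled).
#' @param params an [EnergyParams-class] object.
#' @return replication rates, > 0.
#' @export
replicability <- function(pfold, length, params = energyParams()) {
  stopifnot(is(params, "EnergyParams"))
  params@g * (params@l + (1 - pfold)) / (params@b1 + params@b2 * length)
}

#' Reverse complement of RNA sequences
#'
#' Watson-Crick antiparallel copying: A<->U, G<->C, order reversed. With
#' `reverse = FALSE` the plain (parallel) complement is returned instead.
#'
#' @param x character vector of RNA sequences.
#' @param reverse reverse the complement (the default, chemically standard
#'   antiparallel convention).
#' @return character vector of complements.
#' @examples
#' rnaReverseComplement("AUGC")  # "GCAU"
#' @export
rnaReverseComplement <- function(x, reverse = TRUE) {
  .check_rna(x)
  s <- Biostrings::RNAStringSet(x)
  out <- if (reverse) Biostrings::reverseComplement(s) else Biostrings::complement(s)
  as.character(unname(out))
}

# ---- backends -------------------------------------------------------------

#' Built-in folding backend (base-pair maximization)
#'
#' A deterministic, dependency-free engine: dynamic-programming base-pair
#' maximization over Watson-Crick and GU wobble pairs with a minimum hairpin
#' loop of 3 unpaired bases, assigning -1 kcal/mol per pair. It is fast and
#' fully reproducible across platforms, which makes it the default engine
#' for simulations and tests; it is not a thermodynamic model.
#'
#' @return a [FoldingBackend-class].
#' @export
toyFoldingBackend <- function() {
  new("FoldingBackend", name = "toy", version = "bp-max/1",
      foldFun = function(seqs) {
        r <- cpp_fold_toy(seqs)
        data.frame(structure = as.character(r$structure),
                   energy = as.numeric(r$energy))
      })
}

.vienna_version <- function() {
  out <- tryCatch(system2("RNAfold", "--version", stdout = TRUE, stderr = TRUE),
                  error = function(e) NULL)
  if (is.null(out) || !length(out)) return(NA_character_)
  sub("^RNAfold\\s*", "", out[1])
}

#' ViennaRNA folding backend
#'
#' Thermodynamic minimum-free-energy folding through the `RNAfold` command
#' line tool (default temperature and parameter set; lone-pair and
#' dangling-end conventions are whatever the installed ViennaRNA defaults
#' give). The backend name and version are recorded in run metadata since
#' MFE structures can differ between ViennaRNA releases.
#'
#' @param exe path to the `RNAfold` executable.
#' @return a [FoldingBackend-class].
#' @export
viennaFoldingBackend <- function(exe = "RNAfold") {
  if (!nzchar(Sys.which(exe)))
    stop("RNAfold executable not found; install ViennaRNA or use toyFoldingBackend()",
         call. = FALSE)
  force(exe)
  new("FoldingBackend", name = "vienna", version = .vienna_version(),
      foldFun = function(seqs) {
        out <- system2(exe, c("--noPS"), stdout = TRUE,
                       input = paste(seqs, collapse = "\n"))
        # RNAfold emits two lines per input: sequence, then "structure (energy)"
        if (length(out) != 2L * length(seqs))
          stop(sprintf("RNAfold failed on a batch of %d sequences (first: '%s')",
                       length(seqs), seqs[1]), call. = FALSE)
        res <- out[seq(2L, length(out), by = 2L)]
        structure <- sub("^(\\S+).*$", "\\1", res)
        energy <- as.numeric(sub("^\\S+\\s+\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", res))
        if (anyNA(energy))
          stop(sprintf("could not parse RNAfold output for sequence '%s'",
                       seqs[which(is.na(energy))[1]]), call. = FALSE)
        data.frame(structure = structure, energy = energy)
      })
}

#' Select a folding backend by name
#'
#' @param name `"toy"` or `"vienna"`.
#' @return a [FoldingBackend-class].
#' @export
foldingBackend <- function(name = c("toy", "vienna")) {
  name <- match.arg(name)
  switch(name, toy = toyFoldingBackend(), vienna = viennaFoldingBackend())
}

#' Fold RNA sequences to their MFE structure
#'
#' Maps each sequence to its minimum-free-energy secondary structure and
#' free energy through the given backend. Results are memoized by sequence
#' string in `cache` (an environment) when one is supplied: repeated folding
#' of the same sequence is a lookup, and cached results are identical to
#' uncached ones.
#'
#' @param seqs character vector of RNA sequences over {A,C,G,U}.
#' @param backend a [FoldingBackend-class].
#' @param cache optional environment used as a fold memo.
#' @return `data.frame` with columns `sequence`, `structure`, `energy`.
#' @examples
#' foldSequences("GGGGGAAAACCCCC", toyFoldingBackend())
#' @export
foldSequences <- function(seqs, backend = toyFoldingBackend(), cache = NULL) {
  stopifnot(is(backend, "FoldingBackend"))
  .check_rna(seqs)
  n <- length(seqs)
  structure <- character(n)
  energy <- numeric(n)
  todo <- rep(TRUE, n)
  if (!is.null(cache)) {
    for (i in seq_len(n)) {
      hit <- cache[[seqs[i]]]
      if (!is.null(hit)) {
        structure[i] <- hit$structure
        energy[i] <- hit$energy
        todo[i] <- FALSE
      }
    }
  }
  if (any(todo)) {
    uq <- unique(seqs[todo])
    r <- backend@foldFun(uq)
    if (!is.data.frame(r) || nrow(r) != length(uq))
      stop(sprintf("folding backend '%s' failed (sequence '%s')",
                   backend@name, uq[1]), call. = FALSE)
    idx <- match(seqs[todo], uq)
    structure[todo] <- r$structure[idx]
    energy[todo] <- r$energy[idx]
    if (!is.null(cache)) {
      for (k in seq_along(uq))
        cache[[uq[k]]] <- list(structure = r$structure[k], energy = r$energy[k])
    }
  }
  data.frame(sequence = seqs, structure = structure, energy = energy)
}
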