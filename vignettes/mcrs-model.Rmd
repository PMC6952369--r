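---
title: "The sequence-explicit metabolically coupled replicator system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sequence-explicit metabolically coupled replicator system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcrs)
```

## The model

`mcrs` simulates a community of RNA replicators bound to a mineral surface,
represented as a toroidal square lattice in which each site is empty or
holds one single-stranded RNA molecule. The community persists only through
metabolic cooperation: three essential ribozyme activities (E1, E2, E3)
must all be present in the local neighborhood of a replicator for nucleotide
monomers — and hence replication — to be available there. Strands carrying
no catalytic site are parasites: they consume monomers without contributing.

What distinguishes the model from earlier replicator ecologies is that every
dynamical parameter of a strand is derived from its explicit nucleotide
sequence and minimum-free-energy (MFE) secondary structure:

* **Folding probability.** With Gibbs free energy $E$ of the MFE structure,
  $p_{fold} = e^{-cE} / (1 + e^{-cE})$. With the conventional $c = 0.3$ a
  strand at $E = 0$ is folded half the time and a strand at the empirical
  energy floor $E_{min} = -25$ kcal/mol essentially always.
* **Degradation.** $p_{deg} = \delta_0 - \delta_1 E / E_{min}$ per
  generation: compactly folded strands resist hydrolysis.
  $\delta_0 > \delta_1 \ge 0$, so nothing is immortal. Energies below
  $E_{min}$ are clamped (the floor is empirical, not a hard bound).
* **Replicability.** Only the unfolded state can serve as a template, and
  copying time grows with length $L$:
  $R = g\,(l + (1 - p_{fold})) / (b_1 + b_2 L)$, with $l > 0$ so even the
  most stable folds replicate occasionally.
* **Catalytic activity.** Activity E1 requires an exact 5-base motif wholly
  within non-paired positions outside hairpin loops; E2 and E3 require
  4-base motifs inside hairpin loops of characteristic size (5 and 9 nt).
  Imperfect sites are penalized multiplicatively (see below), giving a
  specific activity $\alpha \in [0, 1]$, and a strand carrying $\sigma$
  sites in total has each actual activity reduced sub-additively,
  $a_i = p_{fold}\,\alpha_i / m^{\sigma - 1}$ — cis-promiscuity is costly.

Replication into an empty site is competitive. Each occupied neighbor $f$
claims the site with weight $C_f = M_f R_f$, where
$M_f = [\prod_i \sum_{j \in \Delta_h(f)} a_{i,j}]^{1/3}$ is the geometric
mean of the three activity sums over $f$'s metabolic neighborhood: if any
essential activity is locally absent, $M_f = 0$ and $f$ cannot replicate.
The empty site itself claims $C_e$, so the replication probability of $f$
is $C_f / (C_e + \sum_j C_j)$. Copying is template-directed: the daughter
is the reverse complement of the template, subject to per-base substitution,
insertion and deletion. Because the two strands of a replicator generally
fold differently, catalytic repertoires alternate between generations —
the origin of trans-promiscuity in the evolved communities.

A generation consists of $W \times H$ elementary updates on uniformly drawn
sites ("each site once on average", i.e. drawn with replacement), followed
by Toffoli–Margolus diffusion: the torus is partitioned into $2 \times 2$
blocks (offset alternating between sweeps) and each block rotates 90° in a
random direction; $\lfloor D \rfloor$ sweeps plus a Bernoulli($D - \lfloor
D \rfloor$) extra one. Diffusion permutes occupants and conserves them
exactly.

## Folding backends

Folding is pluggable behind a deterministic interface
(`FoldingBackend`): the production backend shells out to ViennaRNA's
`RNAfold` (default temperature and parameter set; backend name and version
are recorded in run metadata because MFE structures differ between
releases), and the built-in `toy` backend is a base-pair-maximization
dynamic program (Watson–Crick plus GU wobble, minimum hairpin loop 3,
−1 kcal/mol per pair, deterministic tie-breaks). The toy backend is the
default for simulations and tests: it is orders of magnitude faster, has
no external dependency, and preserves the qualitative structure the model
needs (stems, hairpin loops, energy roughly proportional to pairing).
It is not a thermodynamic model, and absolute energies are not comparable
with ViennaRNA's. All folds are memoized by sequence string — a lattice
run folds each distinct sequence once.

## Parameters and calibration

The printed, fixed quantities of the reference setting are kept as stated:
$c = 0.3$, $E_{min} = -25$ kcal/mol, lengths 15–75 nt, a $300 \times 300$
torus (90,000 elementary updates per generation), $D \in \{1, 4\}$,
$b_2 \in \{0.005, 0.01\}$, initial occupancy 0.8 with half the occupants
catalytically active, and low initial mutation rates
$p_{sub} = 0.005$, $p_{ins} = p_{del} = 0.0005$.

The remaining constants are not printed anywhere we could consult, so the
package fixes its own defaults, chosen once so that the baseline system
reproduces the model's defining phenomena and then frozen:

| parameter | default | role |
|---|---|---|
| $\delta_0$, $\delta_1$ | 0.02, 0.014 | degradation scale and energy benefit |
| $g$, $l$, $b_1$ | 10, 0.3, 1 | replicability scale, folded residual, fixed copy time |
| $C_e$ | 2 | claim of an empty site |
| $m$ | 2 | cis-promiscuity penalty base |
| $h$, repl. radius | 1, 1 | $3\times3$ metabolic and 8-cell replication neighborhoods |
| motifs | GUGGA / AUCG / GGAC | E1 unpaired-region; E2, E3 hairpin loops (5, 9 nt) |
| penalties | E1 exact; E2/E3: 0.25 per mismatch (max 1), 0.5 per nt loop deviation (max 2) | specific activity $\alpha$ |

The calibration targets were qualitative and joint: (i) a persistent
community retaining all three activities with parasites held in check;
(ii) an error threshold exists — a community of pure mutational noise
collapses; (iii) evolved free energies drift toward $E_{min}$; (iv)
communities that evolved at low mutation rates tolerate at least as much
mutation as naive ones. These four constraints are surprisingly
informative. A mismatch penalty as mild as 0.5 lets randomly generated
sequences carry so much accidental activity that metabolism never fails
and no threshold exists (violating ii); tolerating no mismatches at all
makes ribozyme function so brittle that evolved communities are *more*
mutation-sensitive than naive ones (violating iv). The steep-but-graceful
0.25 schedule satisfies both. Similarly, E1's motif must not contain a
complementary base pair at span four (GUGGA does not), or a
pair-maximizing MFE engine could never leave it unpaired.

Two structural choices deserve note. First, the initializer draws active
occupants uniformly from three verified generator templates (one per
activity, constructed and checked against the configured backend at run
time) and fills inactive occupants with random sequences re-sampled until
they carry no catalytic site: "inactive" means inactive, which is what
makes occupancy × active-fraction = 40% of sites metabolically active at
$t = 0$ exact in expectation. Second, the complement orientation is the
antiparallel reverse complement (the chemically standard reading of
Watson–Crick copying, consistent with palindromes being their own
complements); a plain-complement option exists in
`rnaReverseComplement()`.

## Numerical conventions

* Site detection reports at most one site per activity per structural
  element — the highest-$\alpha$ window, ties to the leftmost — so output
  is deterministic and order-independent. Zero-$\alpha$ sites are never
  emitted. Two same-activity sites on one strand both count toward
  $\sigma$ but only the better $\alpha$ contributes.
* The promiscuity divisor is $m^{\sigma-1}$, so a mono-active strand is
  unpenalized and the penalty applies to genuinely promiscuous strands.
* Mutation is a single categorical draw per template base
  (faithful/substitute/delete/insert-before, probabilities
  $1 - p_{sub} - p_{del} - p_{ins}$, $p_{sub}$, $p_{del}$, $p_{ins}$),
  plus one trailing insertion opportunity; substitutions are uniform over
  the three other bases. Products outside 15–75 nt are failed
  replications: the site stays empty and the failure is logged.
* The update schedule draws sites with replacement; all $W H$ updates run,
  then diffusion. The focal site is included in its own $\Delta_h$ sum.
* Degradation clamps $E$ into $[E_{min}, 0]$ before the affine map, so
  $p_{deg} \in [\delta_0 - \delta_1, \delta_0]$ always.
* PCoA is classical scaling with negative eigenvalues truncated to zero;
  sequence dissimilarity is Levenshtein edit distance (indels make strand
  lengths unequal; on equal-length ungapped pairs it equals the Hamming
  distance).
* All randomness flows through R's RNG: `set.seed()` makes an entire run,
  sweep or analysis reproducible, including inside the compiled core.
  Scenario sweeps draw per-replicate seeds up front from the master seed.

## The error-threshold harness

`runScenario()` sweeps effective mutation rates (the sum
$p_{sub} + p_{ins} + p_{del}$, partitioned 10:1:1 like the initiation
rates). The *non-adaptive* scenario applies the target rate from
generation 0; the *pre-adaptive* scenario first runs a burn-in at the low
initiation rates until replicator properties have converged, then switches.
A replicate survives if at least 1% of sites remain occupied at the horizon
*and* at least one replication occurred in the final 100 generations; both
constants are configurable, since the published experiments do not define
their survival rule. `estimateThreshold()` reads the threshold off the
sweep as the largest rate whose surviving fraction reaches a level
(default 1/2).

## Desk-scale study sizes

The reference experiments (a $300 \times 300$ torus over $2.5 \times 10^6$
generations; 35-replicate sweeps over $10^5$ generations) are far beyond a
desk run. The package's tests and the acceptance script instead use sizes
chosen so the full battery completes in well under an hour: ecology runs on
a $50 \times 50$ torus for 5000 generations (5 seeds), and sweeps use 3
rate levels × a handful of replicates with a 2000-generation horizon and a
1500-generation burn-in. At these sizes the qualitative phenomena (i)–(iv)
above are reproduced; the printed full-scale threshold values
(0.026 / 0.066) are not expected to transfer to the toy backend at desk
scale and are not asserted.

## What the synthetic populations do and do not show

The initializer emulates the layered random start of the reference runs:
random placement, over-represented functional ribozymes, random parasite
sequences. It does not emulate real RNA pools (no GC bias, no length
structure beyond the uniform draw) and the toy backend does not emulate
real thermodynamics. Passing tests therefore demonstrate the *dynamical*
claims — metabolic veto, group selection against parasites, the
energy-degradation-replicability trade-off, threshold behavior — not
quantitative agreement with laboratory RNA folding.

## Known limitations

* Strand-separation thermodynamics after copying are disregarded, as in
  the reference model; template and copy simply occupy different sites.
* Metabolism is implicit: no metabolite concentrations, only the
  completeness veto through $M_f$.
* The toy backend's energies are integers (−1 per pair); histograms binned
  below 1 kcal/mol are degenerate under it.
* `estimateThreshold()` is a grid read-off, not an interpolator; its
  resolution is the rate grid.
* Desk-scale evolved strand lengths (typically 40–60 nt) sit somewhat above
  the 35–45 nt band of the full-scale reference runs; the toy backend's
  linear energy-length relation is the likely cause.
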