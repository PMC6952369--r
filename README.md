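# mcrs

Stochastic lattice simulation of prebiotic RNA replicator ecology, with
every dynamical parameter derived from explicit nucleotide sequences and
their minimum-free-energy (MFE) secondary structures.

## The problem

A central puzzle of the RNA World is how a community of short, error-prone
replicators can jointly store more information than any single strand could
sustain below the error threshold. The Metabolically Coupled Replicator
System (MCRS) answers with obligate metabolic cooperation on a surface:
three ribozyme activities (E1–E3) must all be present in a replicator's
local neighborhood for monomer production — and hence replication — to
happen there. Parasites (strands with no catalytic site) free-ride but are
held in check by spatial group selection.

`mcrs` implements the sequence-explicit version of this model for
researchers in prebiotic evolution and replicator ecology. Each strand on a
toroidal grid is an RNA sequence; its MFE structure and Gibbs free energy
$E$ set its

- folding probability $p_{fold} = e^{-cE}/(1+e^{-cE})$,
- degradation probability $p_{deg} = \delta_0 - \delta_1 E/E_{min}$,
- replicability $R = g\,(l + (1-p_{fold}))/(b_1 + b_2 L)$,
- catalytic activities $a_i = p_{fold}\,\alpha_i / m^{\sigma-1}$, where
  $\alpha_i$ comes from motif/loop matching on the structure and $\sigma$
  counts catalytic sites (cis-promiscuity penalty).

Replication into an empty site is claim-proportional,
$P_f = C_f/(C_e + \sum_j C_j)$ with $C_f = M_f R_f$ and $M_f$ the geometric
mean of neighborhood activity sums; copies are mutated reverse complements;
diffusion is the Toffoli–Margolus block rotation.

Folding is pluggable: ViennaRNA (`RNAfold`) or a fast built-in
base-pair-maximization engine (the default for simulation and testing).

## A worked example

```r
library(mcrs)
set.seed(7)
p   <- simParams(width = 50, height = 50)   # 50 x 50 torus, default model
lat <- initPopulation(p)                    # 80% occupied, half active
occupiedFraction(lat)
#> [1] 0.7952
out <- runSimulation(lat, generations = 5000, recordEvery = 1000)
tail(out$trajectory[, c("t", "population", "freqE1", "freqE2", "freqE3",
                        "freqP", "meanLength", "meanEnergy")], 3)
#>      t population freqE1 freqE2 freqE3  freqP meanLength meanEnergy
#> 4 3000       2175 0.0372 0.1356 0.0520 0.6300   47.61057  -15.70851
#> 5 4000       2264 0.0404 0.1496 0.0632 0.6340   50.96511  -16.98322
#> 6 5000       2317 0.0452 0.2272 0.0788 0.5612   58.17264  -19.76694
```

After 5000 generations the community is persistent (~93% of sites
occupied), all three essential activities coexist with a majority of
parasites, and the mean free energy has fallen from about −10 to −19.8
kcal/mol — the population evolves toward compact, degradation-resistant
folds while staying short enough to replicate. Analysis helpers include
`summarizeLattice()`, `pairMatrix()` (activity classes of complementary
strand pairs), `energyHistogram()`, and `pcoaCoordinates(distanceMatrix(...))`
for the quasispecies structure of sequence samples. `runScenario()` /
`estimateThreshold()` run the empirical error-threshold sweeps
(non-adaptive vs pre-adaptive). A command-line wrapper with `simulate`,
`resume`, `sweep`, `analyze`, `pcoa` and `fold-props` subcommands lives at
`inst/cli/mcrs.R`.

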