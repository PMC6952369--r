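Package: mcrs
Title: Sequence-Explicit Metabolically Coupled Replicator System Simulation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic cellular-automaton simulation of prebiotic RNA replicator
    communities on a toroidal mineral surface. Each replicator is an explicit RNA
    sequence whose minimum-free-energy secondary structure determines its folding
    probability, degradation rate, replicability and metabolic ribozyme activities;
    replication copies the reverse complement with point mutations, and local
    metabolic cooperation of three essential ribozyme activities gates replication.
    Includes a pluggable RNA-folding backend (ViennaRNA or a built-in base-pair
    maximization engine), Toffoli-Margolus diffusion, an error-threshold experiment
    harness, and analysis tools (activity-pair matrices, free-energy histograms,
    edit-distance PCoA of sequence samples).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Software, SystemsBiology, Ecology, SequenceMatching
RoxygenNote: 7.3.3
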