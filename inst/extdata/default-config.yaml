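grid:
  width: 300
  height: 300
neighborhoods:
  metabolicRadius: 1
  replicationRadius: 1
dynamics:
  claimEmpty: 2.0
  diffusion: 1.0
  m: 2.0
mutation:
  pSub: 0.005
  pIns: 0.0005
  pDel: 0.0005
lengths:
  min: 15
  max: 75
init:
  occupancy: 0.8
  activeFraction: 0.5
energy:
  c: 0.3
  delta0: 0.02
  delta1: 0.014
  Emin: -25.0
  g: 10.0
  l: 0.3
  b1: 1.0
  b2: 0.01
backend: toy
activities:
- index: 1
  context: unpaired-region
  motif: GUGGA
  targetLoopSize: 5
  mismatchFactor: 0.5
  maxMismatch: 0
  loopSizeFactor: 0.5
  maxLoopDeviation: 2
- index: 2
  context: hairpin-loop
  motif: AUCG
  targetLoopSize: 5
  mismatchFactor: 0.25
  maxMismatch: 1
  loopSizeFactor: 0.5
  maxLoopDeviation: 2
- index: 3
  context: hairpin-loop
  motif: GGAC
  targetLoopSize: 9
  mismatchFactor: 0.25
  maxMismatch: 1
  loopSizeFactor: 0.5
  maxLoopDeviation: 2
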