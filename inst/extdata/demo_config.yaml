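seed: 1.0
simulate:
  nGenes: 2000.0
  nPlanted: 40.0
  kdEffect: 1.0
  kdNoiseSd: 0.25
  kdPerGroup: 5.0
  tumorShift: 1.0
  pairedPatients:
  - 24.0
  - 19.0
  - 24.0
  - 22.0
  pairedNoiseSd: 0.3
  patientEffectSd: 1.0
  betaPerGene: 0.25
  nTrain: 150.0
  nValidation: 200.0
  survivalNoiseSd: 1.0
preprocess:
  detectionThreshold: 4.0
  minFraction: 0.6666667
  dedupMode: strict
de:
  nPermutations: 200.0
  fdrThreshold: 0.05
  fcThreshold: 1.1
  s0: auto
signature:
  minSupport: 3.0
  tumorConcordance: same
scoring:
  thresholdRule: median
  standardize: training
  tiesMethod: efron
resampling:
  nResamples: 200.0
  excludeSignature: no
  mode: train-test
enrichment:
  nRandomSets: 5.0
  randomSetSize: 50.0
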