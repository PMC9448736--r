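seed: 42
nKinases: 5
nSites: 20
edgesPerKinase: 4.0
sharedSubstrateProb: 0.2
conditions:
  control: 2
  treated: 2
baselineLogMean: 13.815510557964274
baselineLogSd: 1.0
noiseSd: 0.25
missingProb: 0.1
nPlanted: 1
kappa: 8.0
nNullGenes: 10
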