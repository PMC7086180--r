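# Example pipeline configuration: all-synthetic run with small problem
# sizes. Paths under `inputs:` may replace the synthetic stage with real
# data (aligned FASTA + clade map, MTX/TSV counts + cell labels, a
# property table and a receptor tree).
seed: 42
outputDir: nachrevo_run
stages:
  synthetic: true
  seqdiv: true
  coexpression: true
  functional: true
parameters:
  deletionMode: pairwise
  coverage: 0.95
  thresholds: [10, 100, 1000]
  detectionFloor: 0.1
  ec50Component: high
  pcaScale: covariance
  model: poisson
  sim:
    nSites: 200
    propType2: 0.2
    nTaxaPerClade: 6
    nCellsPerType: 50
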