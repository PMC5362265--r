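# Demo configuration for the PICTquant pipeline: two conditions (all prey
# recruited vs none), three biological replicates of two small fields each.
seed: 1
scene:
  imageShape: [128, 128]
  nCells: 4
  cellRadius: 14
  backgroundSmoothness: 20
conditions:
  - name: wt_starved
    recruitedFraction: 1.0
  - name: wt_rich
    recruitedFraction: 0.0
nReplicates: 3
nFields: 2
reference: wt_starved
compare: wt_rich
scoring:
  areaMode: overlap
dynamics:
  slowThreshold: 0.2
chip:
  referenceCondition: rich
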