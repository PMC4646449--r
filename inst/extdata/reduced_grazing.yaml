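# Example scenario definition: a 10% reduction in grazed land, split 7%
# to moorland and 3% to open-canopy woodland.
name: reduced_grazing
rules:
- source: grazed
  dest: moorland
  fraction: 0.07
- source: grazed
  dest: open_canopy
  fraction: 0.03
n_seeds: 20
growth_prob: 0.25
connectivity: 8
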