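# Desk-scale study configuration: one synthetic species on a 16 x 16
# grid, 200 burn-in years, three scenario replicates of severe warming.
species:
  preset: synthetic
genetics:
  mu: 0.001
  v: 0.05
fixture:
  grid_shape: [16, 16]
sim:
  seed: 1
  replicates: 3
  burn_in_years: 200
  severity: severe
  vs_multiplier: 1
  single_genotype: false
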