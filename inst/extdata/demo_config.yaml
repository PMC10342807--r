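# Demo run on synthetic inputs: a 7-treated / 10-control study with a
# sparse treatment effect and a sex effect, a random pathway collection,
# a 12-profile disease composite target and a 20-compound library.
seed: 1
z_threshold: 2
som:
  rows: 10
  cols: 10
  epochs: 5
  n_perm: 200
  mode: regress
enrichment:
  n_null: 500
embedding:
  transform: chord
  restarts: 3
simulate:
  n_genes: 2000
  n_treated: 7
  n_control: 10
  effect_fraction: 0.05
  effect_size: 2
  sex_effect_size: 1
  noise_sd: 1
  n_sets: 150
  size_range: [10, 100]
  n_disease_profiles: 12
  shared_fraction: 0.5
  n_drugs: 20
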