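# Example experiment configuration. Any key omitted keeps its default.
seed: 1
threshold: 0.5
strategies: [ens, mars, mann, rivpacs-dfa, rivpacs-rf]
filter:
  min_occurrences: 2
  r_threshold: 0.8
ens:
  n_repeats: 10
  tss_primary: 0.8
  tss_fallback: 0.7
mars:
  penalty: 2
  select_penalty: false
mann:
  hidden_grid: [0, 1, 3, 5, 7, 10]
  decay_grid: [0.001, 0.003, 0.01, 0.03, 0.1]
  n_restarts: 10
rivpacs:
  beta: -0.6
  n_groups: 6
benchmark:
  n_sites: 128
  n_season: 79
  n_method: 33
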