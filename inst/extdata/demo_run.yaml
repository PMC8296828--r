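# Demo configuration: a small synthetic study with two planted driver nodes.
simulate:
  n_genes: 1000
  n_nodes: 12
  n_driver_nodes: 2
  targets_per_node: 40
  driver_enrichment: 0.6
  de_effect_lfc: 1
  noise_sd: 0.5
  n_prone_genes: 60
  n_resistant_genes: 30
  background_rate: 0.4
thresholds:
  fc_up: 1.25
  fc_down: 0.75
  p_max: 0.05
  hct_cutoff: 95
  q_sig: 0.05
species: mouse
seed: 42
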