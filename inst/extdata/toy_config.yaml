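# Toy end-to-end configuration: a scaled-down cohort that exercises every
# pipeline stage in seconds while keeping the planted structure (DE genes,
# coexpression modules, cis pairs, duplex pairs) intact.
seed: 1
top_k: 100
sim:
  n_genes: 150
  n_lnc: 50
  n_per_group: 6
  de_fraction: 0.25
  log2fc_effect: 2
  noise_sd: 0.3
  module_spec:
    - size: 12
      r: 0.9
    - size: 12
      r: 0.9
  seed: 1
  n_cis_pairs: 4
  n_duplex_pairs: 4
  complement_len: 25
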