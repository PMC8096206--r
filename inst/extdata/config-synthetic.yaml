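# bundled synthetic pipeline configuration: desk-scale stand-in for the
# two-phenotype breast-tissue study (113 healthy / 217 tumor samples)
seed: 1
simulate:
  n_genes: 2000
  n_samples:
    healthy: 113
    tumor: 217
  noise_sd: 0.3
  global_factor_sd: 0.05
network:
  measure: mi
  top_k: 5000
  n_permutations: 10000
communities:
  algorithm: louvain
de:
  lfc_cut: 0.5
  p_cut: 0.05
enrichment:
  alpha: 0.005
  min_term: 10
  min_community: 5
  n_terms: 60
cna:
  alpha: 0.05
  n_del_modules: 10
  n_amp_peaks: 8
ctcf:
  flank: 50000
  n_peaks: 3000
regulons:
  n_tfs: 3
  targets_per_tf: 24
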