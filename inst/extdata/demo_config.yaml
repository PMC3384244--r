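# Demo pipeline configuration: canonical calibrated parameter fixture,
# the four shipped feedback variants, and the standard induction protocol
# (1 mM IPTG at 2 h, 12-h batch).
parameters:
  mu0: 0.6
  K_tetR: 20
  K_stress: 400
variants:
  - label: NO_FB
    promoter_scale: 0
    rbs_scale: 1
  - label: WT_STRONG
    promoter_scale: 1
    rbs_scale: 1
  - label: MUT_STRONG
    promoter_scale: 0.30
    rbs_scale: 1
  - label: MUT_WEAK
    promoter_scale: 0.25
    rbs_scale: 0.5
schedule:
  iptg_conc: 1
  t_induce: 2
  t_end: 12
stages: [generate, simulate, fit, sensitivity]
generate:
  n_clones: 4
  fluor_cv: 0.1
  od_cv: 0.05
  fraction_sd: 0.05
  sigma_promoter: 0.25
  sigma_rbs: 0.25
  sigma_mu: 0.08
fit:
  free: [k_tx_R, K_tetR, k_agg]
  n_starts: 3
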