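# Default calibrated parameters of the stochastic clock network.
# Rates in 1/h (bimolecular: 1/(molecule*h)); K_* in molecules; x0_* counts.
theta:
  gon_frq: 0.735238095238
  goff_frq: 0.551428571429
  K_frq: 120
  h_frq: 8
  km_frq: 220.571428571
  dm_frq: 0.275714285714
  kp_frq: 0.459523809524
  dp_frq: 0.275714285714
  gon_wc1: 2.94095238095
  goff_wc1: 1.47047619048
  km_wc1: 165.428571429
  dm_wc1: 0.275714285714
  kp_wc1: 0.459523809524
  dp_wc1: 0.275714285714
  k_wc2: 165.428571429
  d_wc2: 0.275714285714
  k_bind: 0.000612698412698
  d_wcc: 0.018380952381
  k_inact: 0.00612698412698
  gon_ccg: 2.75714285714
  goff_ccg: 2.75714285714
  K_ccg: 84
  h_ccg: 6
  km_ccg: 266.576612843
  dm_ccg: 0.459523809524
  kp_ccg: 0.551428571429
  dp_ccg: 0.275714285714
  x0_gene: 1
  x0_mrna_frq: 60
  x0_prot_frq: 300
  x0_mrna_wc1: 90
  x0_prot_wc1: 300
  x0_prot_wc2: 450
  x0_wcc: 150
  x0_mrna_ccg2: 100
  x0_prot_ccg2: 200
log_scale:
  - gon_frq
  - goff_frq
  - K_frq
  - km_frq
  - dm_frq
  - kp_frq
  - dp_frq
  - gon_wc1
  - goff_wc1
  - km_wc1
  - dm_wc1
  - kp_wc1
  - dp_wc1
  - k_wc2
  - d_wc2
  - k_bind
  - d_wcc
  - k_inact
  - gon_ccg
  - goff_ccg
  - K_ccg
  - km_ccg
  - dm_ccg
  - kp_ccg
  - dp_ccg
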