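# Panel presets for the six results figures. All figures fix gamma_A = 1,
# gamma_U = 1, sigma_Y = 1, sigma_A = 1, n = 10,000 and a marginal
# missingness of 0.5. Rows select beta_U (with the deterministic
# R_A = 1 - U special case as an extra top row where shown); the within-
# panel axis varies alpha_U (figures 2-4) or beta_A (figures 5-7).
common:
  gamma_A: 1
  gamma_U: 1
  sigma_Y: 1
  sigma_A: 1
  pi_U: 0.5
  target_p_missing: 0.5
  "n": 10000
fig2:
  u_observed: false
  gamma_UA: 0
  beta_A: 0
  beta_UA: 0
  rows_beta_U: [-1, 0, 0.1, 0.5, 1]
  deterministic_row: true
  vary: alpha_U
  vary_grid: [0, 0.1, 0.5, 1]
fig3:
  u_observed: false
  gamma_UA: 0.5
  beta_A: 0
  beta_UA: 0
  rows_beta_U: [-1, 0, 0.1, 0.5, 1]
  deterministic_row: true
  vary: alpha_U
  vary_grid: [0, 0.1, 0.5, 1]
fig4:
  u_observed: true
  gamma_UA: 0
  beta_A: 0
  beta_UA: 0
  rows_beta_U: [-1, 0, 0.1, 0.5, 1]
  deterministic_row: true
  vary: alpha_U
  vary_grid: [0, 0.1, 0.5, 1]
fig5:
  u_observed: false
  gamma_UA: 0
  alpha_U: 0
  beta_UA: 0
  rows_beta_U: [-1, 0, 0.1, 0.5, 1]
  deterministic_row: false
  vary: beta_A
  vary_grid: [0, 0.1, 0.5, 1]
fig6:
  u_observed: true
  gamma_UA: 0
  alpha_U: 0
  beta_UA: 0
  rows_beta_U: [-1, 0, 0.1, 0.5, 1]
  deterministic_row: false
  vary: beta_A
  vary_grid: [0, 0.1, 0.5, 1]
fig7:
  u_observed: false
  gamma_UA: 0.5
  alpha_U: 0.5
  beta_UA: 0
  rows_beta_U: [-1, 0, 0.1, 0.5, 1]
  deterministic_row: false
  vary: beta_A
  vary_grid: [0, 0.1, 0.5, 1]
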