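diatom:
  name: diatom
  mu_max: 0.8
  temp_coeff: 1.066
  t_ref: 20.0
  alpha_light: 2.5
  theta_max: 0.04
  theta_min: 0.004
  chl_psii: 1000.0
  psii_psi_ratio: 1.0
  mn_per_psii: 4
  fe_per_psii: 3
  fe_per_psi: 12
  q_mn_min: 1.0
  q_mn_max: 20.0
  q_fe_min: 3.0
  q_fe_opt: 15.0
  q_fe_max: 40.0
  q_zn_max: 80.0
  q_n_min: 0.05
  q_n_max: 0.17
  q_p_min: 0.003
  q_p_max: 0.012
  q_si_min: 0.04
  q_si_max: 0.18
  vmax_n: 0.272
  vmax_p: 0.0192
  vmax_si: 0.288
  vmax_fe: 10.0
  vmax_mn: 3.0
  vmax_zn: 12.0
  k_n: 1.0
  k_p: 0.0625
  k_si: 4.0
  k_fe: 0.5
  k_mn: 0.2
  k_zn: 0.8
  zn_inhibition_const: 2.0
  zn_hyperacc_threshold: 15.0
  zn_hyperacc_floor: 0.2
  zn_hyperacc_steepness: 2.0
  sod:
    eps_a: 1.0
    kcat_ros: 0.05
    eps_p_max: 0.3
    eps_p_min: 0.05
    mnsod_reliance: 1.0
    mn_per_sod: 1.0
nano:
  name: nano
  mu_max: 1.0
  temp_coeff: 1.066
  t_ref: 20.0
  alpha_light: 3.0
  theta_max: 0.045
  theta_min: 0.0045
  chl_psii: 1000.0
  psii_psi_ratio: 1.0
  mn_per_psii: 4
  fe_per_psii: 3
  fe_per_psi: 12
  q_mn_min: 1.0
  q_mn_max: 18.0
  q_fe_min: 2.5
  q_fe_opt: 12.0
  q_fe_max: 35.0
  q_zn_max: 70.0
  q_n_min: 0.05
  q_n_max: 0.17
  q_p_min: 0.003
  q_p_max: 0.012
  q_si_min: .na.real
  q_si_max: .na.real
  vmax_n: 0.34
  vmax_p: 0.024
  vmax_si: .na.real
  vmax_fe: 16.0
  vmax_mn: 3.5
  vmax_zn: 12.0
  k_n: 0.6
  k_p: 0.0375
  k_si: .na.real
  k_fe: 0.15
  k_mn: 0.15
  k_zn: 0.8
  zn_inhibition_const: 2.0
  zn_hyperacc_threshold: 15.0
  zn_hyperacc_floor: 0.2
  zn_hyperacc_steepness: 2.0
  sod:
    eps_a: 1.0
    kcat_ros: 0.05
    eps_p_max: 0.3
    eps_p_min: 0.05
    mnsod_reliance: 1.0
    mn_per_sod: 1.0
pico:
  name: pico
  mu_max: 1.2
  temp_coeff: 1.066
  t_ref: 20.0
  alpha_light: 3.5
  theta_max: 0.05
  theta_min: 0.005
  chl_psii: 1000.0
  psii_psi_ratio: 1.0
  mn_per_psii: 4
  fe_per_psii: 3
  fe_per_psi: 12
  q_mn_min: 1.0
  q_mn_max: 15.0
  q_fe_min: 2.0
  q_fe_opt: 8.0
  q_fe_max: 30.0
  q_zn_max: 60.0
  q_n_min: 0.05
  q_n_max: 0.17
  q_p_min: 0.003
  q_p_max: 0.012
  q_si_min: .na.real
  q_si_max: .na.real
  vmax_n: 0.408
  vmax_p: 0.0288
  vmax_si: .na.real
  vmax_fe: 20.0
  vmax_mn: 4.5
  vmax_zn: 12.0
  k_n: 0.3
  k_p: 0.01875
  k_si: .na.real
  k_fe: 0.08
  k_mn: 0.1
  k_zn: 0.8
  zn_inhibition_const: 2.0
  zn_hyperacc_threshold: 15.0
  zn_hyperacc_floor: 0.2
  zn_hyperacc_steepness: 2.0
  sod:
    eps_a: 1.0
    kcat_ros: 0.05
    eps_p_max: 0.3
    eps_p_min: 0.05
    mnsod_reliance: 1.0
    mn_per_sod: 1.0
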