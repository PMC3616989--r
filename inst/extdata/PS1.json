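{
  "label": "PS1",
  "kinetic": {
    "alpha_A": 10000,
    "delta_A": 1,
    "alpha_I": 100,
    "delta_I": 100,
    "alpha_AC": 0.1,
    "delta_AC": 10,
    "alpha_CI": 10,
    "delta_CI": 100,
    "tau_ACI": 10,
    "epsilon": 0.001,
    "chi": 0.001,
    "sigma": 1,
    "m": 3,
    "n": 2,
    "rho_RAC": 1,
    "rho_RHO": 1
  },
  "rnai": {
    "k_MA": 17.3,
    "k_MC": 17.3,
    "k_MI": 17.3,
    "d_MA": 17.3,
    "d_MC": 17.3,
    "d_MI": 17.3,
    "k_TA": 2.07681,
    "k_TC": 2.07437,
    "k_TI": 2.59193,
    "d_A": 10,
    "d_C": 10,
    "d_I": 10,
    "d_max": 60,
    "gamma_half": 0.1,
    "h": 4.5,
    "sirna_max": 1,
    "r_sirna": 0.0001
  },
  "signaling": {
    "kappa_RAC": 1,
    "kappa_RHO": 1,
    "beta_RAC": 1,
    "beta_RHO": 1,
    "K_RAC": 1,
    "K_RHO": 1,
    "gamma_RAC": 4,
    "gamma_RHO": 4,
    "v": 1,
    "rac_total": 1,
    "rho_total": 1
  }
}
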