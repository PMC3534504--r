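{
  "model": "reversible_toy",
  "scenario": {
    "input_family": "gaussian",
    "input_params": {"t_dip": 2, "tau_in": 0.8, "amplitude": 2},
    "p": {"k1": 2, "k2": 0.5},
    "y0": {"A": 1, "B": 0},
    "T": 5,
    "n_species_times": 20,
    "n_input_times": 20,
    "sigma": 0.1
  },
  "profile": {"levels": [0.68, 0.9], "parameters": ["k1", "k2"]},
  "coverage": {"n_reps": 50, "levels": [0.68, 0.9], "parameters": ["k1", "k2"]}
}
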