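{
  "spec": {
    "seed": 101,
    "n_residues": 60,
    "pocket_fraction": 0.2,
    "pocket_conservation": 0.9,
    "background_conservation": 0.2,
    "n_decoys": 8,
    "true_energy_percentile": 0.7,
    "n_msa_sequences": 50,
    "mutation_rate": 1
  }
}
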