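{
  "config": {
    "D": 0.004,
    "alpha": 0.8,
    "dt": 0.2,
    "n_steps": 20,
    "n_tracks": 8,
    "sigma_nm": 30,
    "diameter": 1,
    "tethered": true,
    "regime": "mRNA_200ms"
  },
  "config_hash": "1df981bf",
  "seed": 11,
  "package": "tetherSMT",
  "version": "0.1.0",
  "kind": "synthetic_fixture",
  "localization_sigma_nm": 30
}
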