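{
  "name": "example-69khz-v1",
  "sync_interval_s": 0.28,
  "n_data_intervals": 6,
  "base_interval_s": 0.455,
  "step_s": 0.008,
  "n_symbols": 8,
  "checksum_rule": "sum_mod",
  "max_residual_s": 0.0026666666666666666
}
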