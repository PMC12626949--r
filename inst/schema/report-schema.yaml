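# Required fields of a pipeline report JSON.
required:
  - config_hash
  - seed
  - variant
  - scheme
  - classifier
  - n_windows
  - aggregate
aggregate_required:
  - "metric"
  - "mean"
  - "sd"
  - "n"
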