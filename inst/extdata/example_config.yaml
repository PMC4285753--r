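# Example pipeline configuration for a small synthetic run.
seed: 7
n_boot: 1000
n_resamples: 999
n_null: 0
pdm_min_agreement: 10
odm_min_agreement: 7
lambda0: 0.70
scenario:
  nrow: 30
  ncol: 30
  cellsize: 5000
  seed: 7
  crop_fraction: 0.14
  crop_total_ha: 12200
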