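# Demo: simulated cohort emulating a 44 HC / 13 NMOSD-NON / 21 NMOSD-ON
# study, cohort-only mode (the simulated ground-truth D_box serves as the
# measured outcome). Run with:
#   octafd run --config demo_config.yaml --out report/
mode: synthetic
seed: 17
with_images: false
cohort:
  n_hc: 44
  n_nmosd_non: 13
  n_nmosd_on: 21
  inter_eye_corr: 0.6
  edss_dbox_corr: -0.475
quality:
  threshold: 6
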