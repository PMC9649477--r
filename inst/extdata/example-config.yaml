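# Example pipeline configuration: simulated cohort at the default
# (published-summary) generator settings, classified on the ISI-100
# blink-reflex asymmetry index and the MRI asymmetry index.
cohort: simulate
mode: summary
seed: 42
classification:
  isi: 100
  r2brrc_cutoff: 0.75
  mri_cutoff: 0.014
  combine_mode: logistic_score
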