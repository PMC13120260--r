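# Reproduction run configuration for the packaged carp/PFOA kidney fixture.
# The two thyroid morphometric endpoints (cross-sectional area, perimeter)
# decrease under goitrogenic activation, so the fixture tags them with
# direction -1; the other ten features are +1.  Directions live in the CSV;
# `direction_overrides` here would take precedence if set.
features: table1_carp_pfoa.csv   # resolve relative to this file's directory
groups:
  - unexposed
  - PFOA_200ng_L
  - PFOA_2mg_L
mc_reps: 10000
seed: 1
alpha: 0.05
eps_bootstrap: 2000
out_dir: mbindex_out
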