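# Example run configuration: synthetic 4:1 PC:PS bilayer, full analysis.
# Usage: run_pipeline(system.file("extdata", "example_run.yml", package = "lipidion"))
synthetic:
  lipids_per_leaflet: 64
  ps_per_leaflet: 12
  n_frames: 50
  n_ca: 48
  n_cl: 24
  p_phos: 0.4
  p_carb: 0.15
  p_coo: 0.2
  waters_per_lipid: 5
  shell_waters_carbonyl: 2
  shell_waters_phosphate: 3
prep:
  n_pc: 104
  n_ps: 24
  n_water: 4300
lipids_per_leaflet: 64
seed: 1
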