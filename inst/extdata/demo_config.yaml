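# Demo cohort: 40 patients on a small grid, a right-hemisphere critical
# region driving a left-egocentric deficit, and a weak lesion-volume
# nuisance effect.
grid_shape: [20, 20, 10]
voxel_size_mm: [2, 2, 2]
n_patients: 40
critical_region:
  centre_vox: [14, 10, 5]
  radius_mm: 5
territory_seeds:
  - [14, 10, 5]
  - [6, 10, 5]
territory_weights: [1, 1]
lesion_radius_range_mm: [5, 12]
effect_beta: 1.0
volume_gamma: 0.01
noise_sd: 0.1
anisotropy_jitter: 0.1
seed: 17
sheets:
  phenotype: left_ego
  severity_scale: 1.0
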