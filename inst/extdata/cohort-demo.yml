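# Demonstration configuration: a reduced synthetic three-group cohort
# analyzed end to end.  Field size and subject counts are kept small so
# the run finishes in about a minute; drop the `image` block (and raise
# n_subjects) for full-scale 2048 x 2048 px cohorts.
output_dir: dabquant-demo
mpp: 0.5
roi:
  area_mm2: 0.01          # 100 um windows on the reduced field
detection:
  sigma_um: 1.0
  nuclear_threshold: 0.2
  min_area_um2: 16
  max_area_um2: 40
  dab_threshold: 0.2
simulate:
  seed: 7
  image:
    width_px: 640
    height_px: 640
    mpp: 0.5
  groups:
    - label: HV
      n_subjects: 5
      positive_fraction_mean: 0.38
      positive_fraction_sd: 0.31
      cell_density_mean: 2500
      cell_density_sd: 800
    - label: GERD
      n_subjects: 5
      positive_fraction_mean: 0.59
      positive_fraction_sd: 0.28
      cell_density_mean: 2500
      cell_density_sd: 800
    - label: EoE
      n_subjects: 5
      positive_fraction_mean: 0.63
      positive_fraction_sd: 0.29
      cell_density_mean: 2500
      cell_density_sd: 800
  patchiness:
    parent_intensity_mm2: 10
    cluster_radius_um: 100
  stain:
    hematoxylin_od: 0.5
    dab_positive_od: 0.6
    dab_negative_od: 0.05
    noise_sd: 0.02
    nucleus_radius_mean_um: 2.75
    nucleus_radius_sd_um: 0.25
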