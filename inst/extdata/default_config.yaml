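# Default pipeline configuration.  All lengths in nm, forces in pN,
# moduli in Pa.  Every random stage derives its seed from `seed`.
seed: 20220420

generator:
  field_size: [10000, 10000]
  n_plates: 6
  pores_per_plate: 40
  diameter_mean: 158      # wet-fixed peak mean
  diameter_sd: 40
  roundness_mean: 0.83
  roundness_sd: 0.09
  n_gaps: 1
  closed_fraction: 0.05

dehydration:
  lambda_dilation: 1.34   # 34% diameter increase on drying
  edge_fraction: 0.2
  edge_elongation: 1.3
  p_open_on_drying: 0.5

optics:
  modality: SIM
  psf_fwhm: 110
  pixel_size: 30
  photon_budget: 500
  background: 5

sem:
  pixel_size: 10
  noise_sd: 5

segmentation:
  threshold_fraction: 0.5
  min_diameter: 50
  gap_diameter: 350
  connectivity: 8
  afm_depth_fraction: 0.5

matching:
  transform_kind: similarity
  gate: 150

qi:
  enabled: false
  preset: GA
  pixel_size: 30
  tomography_forces: [70, 140, 280]

stats:
  diameter_bin: 10

landmarks_file: null
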