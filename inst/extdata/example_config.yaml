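# Example SpheroidProfiler pipeline configuration.
# Run:  Rscript inst/scripts/spheroidtool.R analyze --config example_config.yaml
schema_version: 1
input:
  stack: sim/phantom_stack.tif        # multi-plane TIFF; or use input.files
channel_role_map:
  DAPI: 1
  pimonidazole: 2
  DRAQ7: 3
  mAG: 4
  mKO2: 5
  PBMC: 6
pixel_size_um: 2                      # overrides TIFF metadata
nuclei_source: DAPI                   # or: {merge: [mAG, mKO2, DRAQ7]}
nuclei:
  diameter_min_px: 3
  diameter_max_px: 16
  threshold_strategy: manual          # automatic = Otsu
  manual_threshold: 300
  declump_smoothing_px: 2
  maxima_min_distance_px: 4
  fill_holes: true
  exclude_border: true
pbmc:
  diameter_min_px: 2
  diameter_max_px: 12
  threshold_strategy: manual
  manual_threshold: 300
secondary:
  max_expansion_px: 5
  guide_threshold_strategy: automatic
spheroid:
  diameter_estimate_px: 280
  threshold_strategy: manual          # manual preferred for the spheroid
  manual_threshold: 200
positivity:
  DRAQ7: {strategy: automatic}
  mAG: {strategy: automatic}
  mKO2: {strategy: automatic}
bin_width_um: 25
normalize: ring_area
analyses:
  hypoxia: true
  death: true
  infiltration: true
  fucci: true
output_dir: out
seed: 1
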