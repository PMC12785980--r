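# Example run configuration for the cxrreason pipeline.
preset: desk
seed: 1
paths:
  data_dir: cohort
  out_dir: runs/desk
training:
  epochs: 5
  batch_size: 8
  lr: 0.001        # paper-preset runs use 1e-4
  weight_decay: 0.0001
  lambda: 0.5      # segmentation weight in the joint objective
  loss: cb_focal   # or "bce"
preprocess:
  clahe:
    tile_size: 8
    clip_factor: 3.0
    levels: 256
  clahe_before_resize: true
phantom:
  image_size: 128
  prevalence: 0.15
  noise_sd: 8
  lesion_intensity: 60
reasoning: {}      # rulebase path override goes under paths: rulebase
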