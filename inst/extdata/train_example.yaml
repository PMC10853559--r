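# Example training configuration for the CLI `train` verb.
batch_size: 16
learning_rate: 0.01
l2: 0.0005
epochs: 30
augment:
  stages: [training, inference]
  rotation_range: 30
  crop_length: 300
  n_crops: 5
  n_rotations: 4
  seed: 1
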