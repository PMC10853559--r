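# Example simulator configuration: a moderate-severity (score ~2) recording.
duration_s: 10
fps: 60
base_frequency: 2.2
base_amplitude: 0.22
decrement_rate: 0.04
hesitation:
  rate: 0.4
  depth: 0.5
  duration_s: 0.4
jitter_sd: 0.01
missing_rate: 0.1
seed: 7
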