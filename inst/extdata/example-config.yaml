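# Example imunet run configuration. Unset keys fall back to package
# defaults; unknown keys are rejected.
generator:
  classes: [downstairs, marching, running, standing, upstairs, walking]
  fs: 20
  noise_sd: 0.08
  n_sessions: 6
  seed: 2024
preprocess:
  fs: 20        # benchmark preset; the 100 Hz hardware preset uses fs: 100
  size: 200
  stride: 100
  cutoff: 2.5
model:
  d_model: 32
  h: 2
  d_ff: 64
  d_s: 8
  c_attn: 8
  dropout: 0
train:
  learning_rate: 0.001
  batch_size: 64
  epochs: 30
  folds: 5
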