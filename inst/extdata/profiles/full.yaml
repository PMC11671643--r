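profile: full
diffusion:
  schedule: linear
  timesteps: 1000
  beta_start: 0.0001
  beta_end: 0.02
noise:
  kind: simplex
  base_frequency: 0.015625   # 2^-6 cycles/pixel
  octaves: 6
  decay: 0.8
model:
  image_size: 256
  base_channels: 128
  channel_mult: [1, 1, 2, 3, 4]
  res_blocks: 2
  attention_resolutions: [32, 16]
  attention_heads: 2
  dropout: 0
training:
  iterations: 100000
  batch_size: 1
  learning_rate: 0.0001
  weight_decay: 0.0
  adam_beta1: 0.9
  adam_beta2: 0.999
  ema_decay: 0.9999
segmentation:
  tau: 0.3
  lambda: 300
  lambda_window: [250, 400]
  ensemble_lambdas: [250, 300, 350, 400]
  kernel: 3
  keep_k: 1
  min_area: 5
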