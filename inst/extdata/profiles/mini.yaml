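profile: mini
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
  image_size: 64
  base_channels: 16
  channel_mult: [1, 2, 2]
  res_blocks: 1
  attention_resolutions: [16]
  attention_heads: 1
  dropout: 0
training:
  iterations: 2000
  batch_size: 1
  learning_rate: 0.0003
  weight_decay: 0.0
  adam_beta1: 0.9
  adam_beta2: 0.999
  ema_decay: 0.995
segmentation:
  tau: 0.3
  lambda: 300
  lambda_window: [250, 400]
  ensemble_lambdas: [250, 300, 350, 400]
  kernel: 3
  keep_k: 1
  min_area: 5
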