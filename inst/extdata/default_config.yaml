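# Desk-scale default run configuration.
# Every numeric default of the pipeline lives here; sections mirror the
# constructors cohort_config / render_config / backbone_config /
# train_run_config / statistics_net_config / mine_train_config.
seed: 1
n: 2000
image_size: 64
split:
  train: 0.7
  val: 0.15
  test: 0.15
render:
  noise_sd: 0.05
  brightness_sd: 0.10
  contrast_sd: 0.12
backbone:
  family: conv
  base_width: 16
  n_stages: 3
  conv_head: [128, 64]
  dropout: 0.3
train:
  learning_rate: 0.001
  weight_decay: 0.00001
  epochs: 10
  batch_size: 32
mine_net:
  hidden_sizes: [256, 64]
  activation: elu
mine_train:
  learning_rate: 0.001
  batch_size: 100
  max_epochs: 200
  ema_decay: 0.99
  n_seeds: 3
  plateau_patience: 20
  val_fraction: 0.2
attributes: [age, sex, IVSDd, LVPWDd, LVIDd]
stages: [early, mid, final]
expected_order: [age, sex, IVSDd, LVPWDd, LVIDd]
n_boot: 1000
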