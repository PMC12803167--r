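# Reference simulation settings
network:
  Nx: 16
  Nz: 16
  gamma: 0.01
train:
  policy_lr: 0.001
  clip_epsilon: 0.2
  entropy_coef: 0.05
  rollout_horizon: 64
  ppo_epochs: 16
  minibatch_size: 64
  n_episodes: 10000
  eval_window: 100
env:
  reward_delay_min: 2
  reward_delay_max: 8
  max_steps: 20
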