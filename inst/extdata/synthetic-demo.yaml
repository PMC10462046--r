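# Demo pipeline: simulate a small synthetic membrane, trace scrambling,
# and reconstruct the flip-flop free-energy profile by WHAM.
name: synthetic-demo
seed: 42
stages: [simulate, scramble, wham]
scenario:
  n_lipids: 64
  barrier: 20
  duration: 500
  snapshot_interval: 10
scramble:
  interval: 10
  smooth: 200
wham:
  n_windows: 31
  samples_per_window: 2000
  reference_barrier: 62
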