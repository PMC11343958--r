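# Epoch scheme for a 64-s recording with a 24-s seizure (20 s ~ 44 s):
# 16-s epochs, three ictal epochs overlapping by 12 s, a 2-s guard band
# around the ictal phase, and 2 s trimmed at each end of the recording.
epochs:
  pre-ictal: [2, 18]
  ictal 1: [20, 36]
  ictal 2: [24, 40]
  ictal 3: [28, 44]
  post-ictal: [46, 62]
ictal: [20, 44]
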