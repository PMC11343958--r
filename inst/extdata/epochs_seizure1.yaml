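# Epoch scheme for a 72-s recording with a 32-s seizure (20 s ~ 52 s):
# 16-s epochs, three ictal epochs overlapping by 10 s, a 4-s guard band
# around the ictal phase, and 2 s trimmed at each end of the recording.
epochs:
  pre-ictal: [2, 18]
  ictal 1: [22, 38]
  ictal 2: [28, 44]
  ictal 3: [34, 50]
  post-ictal: [54, 70]
ictal: [20, 52]
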