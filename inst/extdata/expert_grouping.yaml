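# Expert grouping of the 20 bipolar iEEG channels: seizure-onset area (O),
# propagation area (P), and channels not involved in the seizure (N).
groups:
  "O": [Cp1, Cp4, Pp1, Pp4, Ap2, Ap6, Bp1]
  "P": [Pp8, Dp1, Dp5, Tp1, Fp2]
  "N": [Cp9, Ap11, Bp6, Bp11, Tp8, Hp2, Ip2, Fp8]
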