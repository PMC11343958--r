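# Default pipeline configuration.
num_layers: 1
dropout: 0.5
lr_rate: 0.001
momentum: 0.9
weight_decay: 0.001
bt_sz: 32
seq_len: 50
hidden_dim: 30
num_epoch: 10
n_repeats: 10
phi_G: 0.1
phi_dc: 0.1
lambda: 0.85
excluded_group: "N"
seed: 1
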