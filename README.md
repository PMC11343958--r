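# grugc: effective connectivity and seizure-network analysis via recurrent Granger causality

`grugc` estimates *directed* (effective) connectivity between the channels
of a multichannel intracranial EEG recording and turns it into a
seizure-network analysis: which brain regions behave as seizure-onset
sources, which merely relay activity, and which are targets of
propagation. The intended users are researchers analysing iEEG from
epilepsy patients (e.g. for pre-surgical evaluation of the epileptogenic
zone) and methodologists studying nonlinear Granger-causality estimators,
who need a controlled synthetic test bed as much as the estimator itself.

## The method

**Recurrent Wiener–Granger causality.** Channel *i* Granger-causes channel
*j* if withholding *i*'s history worsens the prediction of *j*'s next
sample. Predictions come from a gated recurrent unit (GRU) — one recurrent
layer plus a linear readout — trained on sliding windows of `seq_len = 50`
samples to predict the following sample. The GRU update at step *t* is

    R_t = sigmoid(X_t W_xr + H_{t-1} W_hr + e_r)        (reset gate)
    Z_t = sigmoid(X_t W_xz + H_{t-1} W_hz + e_z)        (update gate)
    H~_t = tanh(X_t W_xh + (R_t ⊙ H_{t-1}) W_hh + e_h)  (candidate state)
    H_t = Z_t ⊙ H_{t-1} + (1 − Z_t) ⊙ H~_t

Because the recurrent state carries history of arbitrary depth, the
estimator has no fixed model order and can pick up long, heterogeneous
transmission delays — the regime where fixed-order linear
autoregressive Granger methods break down.

For every target *j*, a *full* model (all *m* channels as input) gives a
residual variance σ²(j), and a *restricted* model retrained without
channel *i* gives σ²₋ᵢ(j). The causal strength is the Wiener–Granger index

    c_ij = max(0, ln(σ²₋ᵢ(j) / σ²(j))),   c_ii = 0,

estimated `n_repeats = 10` times with different seeds and averaged. Rows
of the causal matrix **G** are normalized (c\*ᵢⱼ = cᵢⱼ / Σⱼ cᵢⱼ) and
thresholded at φ_G = 0.1 (entries ≥ φ_G become edges) to give the binary
directed graph **G̃** on which all further analysis runs.

**Group analysis.** From in/out degrees, the degree centrality
dcᵢ = (dᵢⁱⁿ − dᵢᵒᵘᵗ)/(dᵢⁱⁿ + dᵢᵒᵘᵗ) classifies each node as onset source
(`O_S`, dc ≤ −φ_dc), propagation-internal (`P_I`), or propagation target
(`P_T`, dc ≥ φ_dc), with φ_dc = 0.1. Against an expert channel grouping
(Onset / Propagation / Not-involved), nodes are marked `T` (consistent),
`F` (misclassified) or `M` (undecided `P_I`), and scored strictly
(Acc1 = #T/N) and leniently (Acc2 = (#T + #M)/N).

**Centrality.** Node importance is ranked by directed betweenness
centrality and by a causal-weighted PageRank: the transition matrix
M = f(Gᵀ ⊙ G̃ᵀ) column-normalizes the surviving causal weights, and
PR is iterated as PR ← λ M PR + (1 − λ)/m with damping λ = 0.85 until the
L1 change falls below 1e−10.

Because clinical iEEG cannot be redistributed, the package ships a
simulator (`simulate_var`, `simulate_seizure_course`) that generates
multivariate time series from a known directed coupling network — linear
or tanh/square transfer per edge, transmission lags up to ~20 samples, a
piecewise variant whose coupling switches across pre-ictal/ictal/post-ictal
phases — plus `recovery_scores` for precision/recall/F1 of edge recovery.

## Worked example

Recover a known 5-node network (mixed lags 1/3/8, one tanh edge):

```r
library(grugc)
spec <- default_network_spec()
rec  <- simulate_var(spec, 2000, seed = 1)
G    <- wgci_matrix(rec, predictor_config(n_repeats = 1, seed = 1))
G
#> <causal_matrix> 5 x 5, averaged over 1 repeat(s)
#>        Ch1    Ch2    Ch3    Ch4   Ch5
#> Ch1 0.0000 0.6718 0.0000 0.0000 0.000
#> Ch2 0.0000 0.0000 0.1049 0.0000 0.000
#> Ch3 0.0000 0.0000 0.0000 0.0223 0.000
#> Ch4 0.0000 0.0000 0.0000 0.0000 0.244
#> Ch5 0.0917 0.0000 0.0000 0.0000 0.000

adj <- binarize(normalize_rows(G), phi_G = 0.1)
str(recovery_scores(adj, truth_adjacency(spec)))
#> List of 4
#>  $ precision: num 1
#>  $ recall   : num 1
#>  $ f1       : num 1
#>  $ hamming  : int 0
```

Every true edge — including the weakly expressed lag-8 link Ch3→Ch4 —
is recovered and no spurious edge survives the threshold (F1 = 1).

Group analysis on a network with a designated driver:

```r
spec <- network_spec(4,
  data.frame(from = c("Cp1", "Cp1", "Cp1", "Pp8"),
             to   = c("Pp8", "Dp1", "Tp1", "Dp1"),
             lag  = c(1, 2, 1, 1), coef = c(0.9, 0.9, 0.8, 0.5)),
  channel_names = c("Cp1", "Pp8", "Dp1", "Tp1"))
rec <- simulate_var(spec, 1500, seed = 2)
G   <- wgci_matrix(rec, predictor_config(n_repeats = 1, seed = 2))
cls <- classify_nodes(node_degrees(binarize(normalize_rows(G), 0.1)), 0.1)
marks <- mark_against_expert(cls, c(Cp1 = "O", Pp8 = "P", Dp1 = "P", Tp1 = "P"))
marks
#>   node cls expert mark
#> 1  Cp1 O_S      O    T
#> 2  Pp8 P_I      P    M
#> 3  Dp1 P_T      P    T
#> 4  Tp1 P_T      P    T
accuracy_scores(marks)
#> acc1 acc2
#> 0.75 1.00
```

The driver `Cp1` is recognised as an onset source, the two sinks as
propagation targets; the relay `Pp8` has balanced degrees and is left
undecided (`M`), so the strict accuracy is 3/4 and the lenient 4/4.

`run_pipeline()` chains all stages per epoch of a recording (EDF or
delimited text) given an epoch scheme and expert grouping
(`inst/extdata/` contains ready-made schemes, the expert grouping and the
default configuration). `inst/cli/grugc` exposes `simulate`, `run`,
`score` and `export` subcommands for shell use.

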