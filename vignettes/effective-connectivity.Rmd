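---
title: "Recurrent Granger causality for seizure-network analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent Granger causality for seizure-network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Intracranial EEG gives millisecond-scale access to the electrical activity
of implanted cortical regions, and the clinical question in drug-resistant
epilepsy is directional: *which* region drives a seizure and *where* does
it propagate. Correlation-based (functional) connectivity cannot answer
that; `grugc` implements an effective-connectivity pipeline built on
Wiener–Granger causality with a recurrent (GRU) predictor.

The Granger principle: channel $i$ causes channel $j$ if the history of
$i$ improves the prediction of $j$'s next sample beyond what all other
channels' histories already provide. Writing $\sigma^2(j)$ for the
next-step prediction-error variance of a model fed all $m$ channels and
$\sigma^2_{-i}(j)$ for a model retrained with channel $i$ withheld, the
causal strength is

$$c_{ij} = \max\!\left(0,\ \ln \frac{\sigma^2_{-i}(j)}{\sigma^2(j)}\right),
\qquad c_{ii} = 0 .$$

The logarithm of a variance ratio is the classical Wiener–Granger index;
the clip at zero discards negative estimates, which can only arise from
estimation noise (removing information cannot truly improve prediction).

The predictor is a single GRU layer (reset gate, update gate, candidate
state) with a linear readout from the final hidden state, trained by
mini-batch gradient descent on the mean-squared next-step error. The
recurrent state gives the model an *adaptive* memory: unlike a
fixed-order vector autoregression it has no built-in maximum lag, so
couplings with long or heterogeneous transmission delays (tens of
samples) are representable as long as they fall inside the input window.

### Assumptions

* Signals are real-valued, equally sampled, and approximately stationary
  *within* an analysis epoch (the pipeline analyses 16-s epochs
  separately precisely because seizures are not globally stationary).
* Causality is identified from predictability; unobserved common drivers
  outside the montage can induce spurious edges, as in every Granger-type
  method.
* Edge strength is relative, not calibrated: thresholds act on
  row-normalized strengths, so only the within-source distribution of
  outgoing influence matters.

## Pipeline stages and their parameters

`wgci_matrix()` → `normalize_rows()` → `binarize()` →
`node_degrees()`/`classify_nodes()`/`mark_against_expert()` →
`betweenness_scores()`/`build_transition()`/`pagerank_scores()`,
orchestrated per epoch by `run_pipeline()`.

The training defaults of `predictor_config()` are the reference settings
used throughout: 1 recurrent layer, hidden dimension 30, input sequence
length 50 samples, 10 training epochs, batch size 32, dropout 0.5 between
recurrent output and readout, AdaBound optimizer with learning rate 1e-3,
first-moment decay 0.9, weight decay 1e-3, and 10 repeat estimations
averaged element-wise. The graph-analysis thresholds are
$\phi_G = 0.1$ (binarization), $\phi_{dc} = 0.1$ (node classification)
and $\lambda = 0.85$ (PageRank damping), all strictly inside $(0,1)$.
At 256 Hz a 50-sample window spans ~195 ms of signal history.

Lowering $\phi_G$ admits weaker edges (denser graphs); since each row of
the normalized matrix sums to at most 1, a row can contribute at most
$\lfloor 1/\phi_G \rfloor$ edges. Lowering $\phi_{dc}$ moves nodes out of
the undecided class into sources/sinks; the boundary cases belong to the
outer classes ($dc \le -\phi_{dc}$ is a source, $dc \ge \phi_{dc}$ a
sink), and a tie at the binarization threshold *keeps* the edge.

## Estimation choices that matter

**Joint versus per-target models.** By default one multivariate model per
input mask predicts all $m$ channels simultaneously ($m+1$ trainings per
repeat instead of $m^2$), with identical residual-variance semantics.
The cost is gradient dilution: when only one target carries learnable
structure, its loss contribution is $1/m$ of the total, and subtle
dependencies (e.g. a solitary long-lag edge) may sit below the
optimization noise floor. `per_target = TRUE` fits scalar-output models
instead — $m$ times more expensive and markedly better at isolated
long-delay couplings; the long-delay validation in the test suite uses
this mode with a 30-epoch schedule for exactly this reason.

**Restricted models are retrained, not masked.** The Wiener–Granger
definition compares two *fitted* models. Zeroing an input channel of the
full model at evaluation time (`restricted_mode = "zero_mask"`) is
offered as a cheap screen but is not equivalent — the remaining weights
were optimized expecting that channel — and stays off by default.

**Averaging before normalization.** The repeat-averaged raw matrices are
averaged first and normalized once. Averaging normalized matrices instead
would weight repeats by their row sums; with a fixed estimator either
choice is defensible, and averaging raw log-ratios keeps the estimate an
unbiased mean of the per-repeat indices.

**Residual variance.** Computed as the mean squared next-step error on
the training windows themselves (no held-out split), with dropout
disabled. MSE-trained predictors leave near-zero-mean residuals, so this
coincides with the error variance up to the mean's negligible square.

**Dropout placement.** Dropout 0.5 is applied between the recurrent
output and the readout only, not inside the recurrent cell, where it
would destroy the state dynamics that the method relies on.

## Numerical choices

* **Coordinates.** Seconds map to 0-based sample indices via
  $\lfloor s \cdot \text{rate} \rfloor$; epochs are half-open
  $[\text{start}, \text{end})$, so a 16-s epoch at 256 Hz is exactly 4096
  samples regardless of its offset.
* **Z-scoring.** Each channel is standardized per epoch before training
  (toggleable). MSE training otherwise weights channels by amplitude, and
  iEEG amplitudes vary across contacts for non-physiological reasons.
* **Initialization.** Weights are uniform $\pm 1/\sqrt{\text{fan-in}}$;
  the update-gate bias starts at $+1$ (the GRU analogue of the customary
  LSTM forget-bias-of-1), putting initial state retention near 0.73 per
  step so gradients can reach dependencies a dozen-plus steps back. With
  a zero bias the effective memory horizon at these training lengths is
  roughly five to eight samples and long-lag couplings are out of reach.
* **Optimizer.** AdaBound: Adam whose element-wise step sizes are clipped
  into a band that tightens around a terminal SGD rate (0.1) as training
  progresses; the configured momentum 0.9 is the first-moment decay,
  $\beta_2 = 0.999$, $\epsilon = 10^{-8}$, band speed $\gamma = 10^{-3}$.
  Weight decay is added to the gradient. `optimizer = "adam"` disables
  the band.
* **Degenerate inputs.** A zero full-model residual variance (perfectly
  predictable channel) raises an error rather than producing infinite
  indices. A causal-matrix row summing to zero stays all-zero under
  normalization — white-noise channels legitimately have no outgoing
  influence, and raising an error there would make clean noise
  unanalysable. The diagonal is zeroed *before* row normalization:
  self-causality is undefined in the index, and including a diagonal
  entry in the row sum would deflate every genuine entry of that row.
* **Isolated nodes.** Degree centrality is $0/0$ for an unconnected
  node; it is defined as 0 (hence `P_I`), since no directional evidence
  exists.
* **Dangling nodes in PageRank.** A node with no surviving out-edges
  leaves an all-zero transition column, which leaks probability mass and
  breaks the sum-to-1 property of the stationary distribution. By
  default such columns are replaced by the uniform distribution
  (standard teleportation); `dangling = "zero"` keeps the literal
  guarded normalization for comparison.
* **Transition weights.** The transition matrix is built from the *raw*
  causal matrix masked by the binary adjacency (element-wise product,
  then column L1-normalization) — an element-wise reading is the only
  one under which the entries are step probabilities. Using the
  row-normalized matrix instead would differ only where a column mixes
  entries from differently scaled rows; column normalization absorbs any
  uniform rescaling (PageRank is scale-invariant, and the suite checks
  this).
* **Betweenness.** Standard Freeman definition on the directed unweighted
  graph: endpoints excluded, unreachable pairs contribute nothing.
  Computation is delegated to igraph and cross-checked in the tests
  against an exhaustive BFS path-count enumeration on every graph size up
  to 9.
* **Seeds.** One master seed derives per-repeat and per-mask training
  seeds through a fixed integer recurrence (kept inside 32-bit range);
  the C++ trainer runs its own Mersenne Twister, so results are
  reproducible regardless of R's RNG state, and the simulator restores
  R's RNG state after use.

## The accuracy rule

Channels classified `O_S` with expert label O, or `P_T` with label P, are
marked `T`; conflicting assignments `F`; undecided `P_I` channels `M`.
Acc1 counts `M` as incorrect (#T/N), Acc2 as correct ((#T+#M)/N), so
Acc1 ≤ Acc2 with equality iff nothing was undecided. A different prose
reading — resolving every undecided channel *into a fixed group* — exists
but is inconsistent with per-group accuracy bookkeeping (an `M` in the
O-group table would then count as correct in one table and incorrect in
the other even when the expert label is the same); the strict/lenient
counting rule is what the package implements and what its tests pin down
against worked per-epoch examples.

## What the synthetic generator emulates — and what it does not

`simulate_var()` draws from
$x_j(t) = \sum_{\text{edges } i\to j} \beta \, g(x_i(t - \ell)) + \varepsilon_j(t)$
with iid Gaussian innovations, per-edge lag $\ell$ (up to ~20) and
transfer $g \in \{\text{identity}, \tanh, (\cdot)^2\}$; stability of the
linearized system is enforced at construction (companion-matrix spectral
radius < 1, with $|\beta|$ bounding the tanh slope) and a burn-in of
$10\times$ the maximum lag is discarded. `simulate_seizure_course()`
concatenates three phases with different coupling networks, carrying
signal state across boundaries, and returns an epoch scheme with one
pre-ictal, three overlapping ictal, and one post-ictal epoch — the
geometry of a clinical epoch table.

This emulates the *causal structure* of multichannel recordings: directed
coupling, delays, nonlinearity, phase switching. It does **not** emulate
electrophysiology: no $1/f$ spectra, oscillatory rhythms, artifacts,
volume conduction, common reference effects, or heavy-tailed noise.
Passing recovery tests therefore demonstrates that the estimator
identifies directed coupling of the simulated kind at realistic sample
sizes — not that it is robust to everything clinical iEEG contains.
The default validation network (`default_network_spec()`) is a 5-node
cycle with coefficients 0.9, lags {1, 3, 8, 1, 3} and one tanh edge —
strong enough to be identifiable from a 16-s-epoch-scale sample, varied
enough to exercise delay spread and nonlinearity.

## Problem sizes used by the validation suite

The suite favours many small, deterministic checks plus a few
training-based properties at desk scale: edge recovery on the 5-node
network at 2000 samples over 5 seeds (single-repeat estimates — the seed
plays the role of the repeat); bivariate direction agreement against an
OLS Granger baseline at 1000 samples; sample-size monotonicity at
500/2000/8000 samples on a 3-node cycle; the long-delay (lag-15) contrast
at 2500 samples in per-target mode; and a 12-channel seizure-course
pipeline smoke run at a reduced sampling rate. Exact/graph-theoretic
properties (betweenness vs enumeration, PageRank vs a direct linear
solve, normalization/thresholding arithmetic, accuracy counting) run
exhaustively at full precision.

## Known limitations

* The memory horizon of the default *joint* training schedule is modest;
  isolated couplings at lags beyond ~10 samples need `per_target = TRUE`
  and a longer schedule (see above). Within-window but very long delays
  are representable, yet optimization — not representation — is the
  binding constraint.
* Edges are thresholded, not significance-tested; $\phi_G$ is a
  sensitivity knob, and rows with no true outgoing influence can promote
  noise entries to edges (the row normalization makes small rows
  unstable). Interpreting sparse rows conservatively is advisable.
* Training-set residual variance slightly favours the full model
  (more inputs, more capacity to overfit); the clip at zero and repeat
  averaging mitigate, but do not remove, the resulting small positive
  bias of weak entries.
* Runtime scales as $(m+1) \times$ repeats $\times$ training cost for
  joint mode and $m^2 \times$ for per-target mode; large montages call
  for the joint default.
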