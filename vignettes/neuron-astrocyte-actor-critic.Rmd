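---
title: "Neuron-astrocyte actor-critic networks: model, training, and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuron-astrocyte actor-critic networks: model, training, and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asnen)
```

# Overview

`asnen` is a simulation and analysis toolkit built around one scientific
question: when an actor-critic agent whose actor is a neuronal population
and whose critic is an astrocytic population is trained on a delayed-reward
sequence task, do the astrocytic units spontaneously develop the
multi-timescale, heterogeneous calcium-like dynamics seen in cerebellar
Bergmann glia during reward learning? The package provides four
ingredients: the task environment, the tripartite-synapse recurrent
network with policy-gradient training (plus vanilla RNN and LSTM
baselines), event-aligned analysis of the internal dynamics, and a fiber
photometry pipeline with a synthetic two-channel generator that serves as
its closed-loop validation.

# The task environment

The task abstracts a rodent arena: the agent starts in a trigger zone
where a brief cue sounds, must move through a fixed transit corridor into
a reward zone, and then must wait through a randomly drawn delay before a
unit reward is delivered, after which a short post-reward period ends the
trial in success. Formally it is a discrete-time MDP with phases TRIGGER
-> TRANSIT -> REWARD_ZONE -> POST_REWARD -> {SUCCESS, FAILURE}, two
actions (move, wait), and a three-component observation: a constant bias
(+1), a transient cue channel, and a reward-delivered flag. Defaults
follow the reference settings: step cost $-0.01$, success reward $+1$,
reward delay drawn uniformly from $\{2,\dots,8\}$ per episode, maximum
trial length 20 steps. The transit corridor is 3 steps (the source states
only "a fixed number of steps"), the cue lasts 1 step, and the post-reward
period 1 step; all are configurable.

Decisions worth knowing:

* Waiting in the reward zone must be *consecutive*: a move resets the
  hold counter but does not leave the zone (the 4-state chain has no
  backward transition).
* The step cost applies to every step taken, including the delivery and
  post-reward steps, so the best achievable return with delay $d$ is
  $1 - 0.01\,(2 + \texttt{transit} + d + \texttt{post})$;
  `optimal_return()` certifies this by exhaustive search and returns `NA`
  when success is unreachable.
* The reward flag switches on at delivery and stays on; the cue channel is
  active for `cue_duration` steps from reset.

# The tripartite network

The recurrent core has three coupled state vectors: neuronal activities
$x \in [0,1]^{N_x}$, a flattened synaptic vector $w \in \mathbb{R}^{N_x^2}$
(reshaped row-major into the recurrent matrix $W$), and astrocytic
activities $z \in \mathbb{R}^{N_z}$, with $N_x = N_z = 16$ in the
reference preset. With discretization step $\gamma$ (0.01) and astrocyte
timescale $\tau \in (0,1)$ (default 0.5), one step computes

$$x_t = (1-\gamma)\,x_{t-1} + \gamma\,\sigma\!\big(W_{t-1} x_{t-1} + W_{in,x}\, o_{t-1}\big)$$
$$w_t = (1-\gamma)\,w_{t-1} + \gamma\big[\sigma(\mathrm{vec}(x_{t-1} x_{t-1}^\top)) \odot \mathrm{vec}(C) + \tanh(D z_{t-1})\big]$$
$$z_t = (1-\gamma)\,z_{t-1} + \gamma\tau\big[\tanh(F z_{t-1}) + \tfrac{1}{N_x}\mathrm{rowsum}\big(H \odot \tanh(x_{t-1} x_{t-1}^\top)\big) + \tanh(W_{in,z}\, o_{t-1})\big]$$

$C$ gates the Hebbian-like outer-product drive on synapses, $D$ maps
astrocytic activity onto synapses, $H$ feeds synaptic coactivation back to
astrocytes, and $F$ couples astrocytes among themselves. The policy is a
softmax readout of the neuronal layer, $\pi = \mathrm{softmax}(W_\pi x_t)$,
and the value estimate is a linear readout of the astrocytic layer,
$V = W_v z_t$ — the actor-critic split is anatomical.

Three modelling choices deserve emphasis because the source prints the
equations without delimiters:

1. **Parenthesization.** The x-update is a leaky integrator with the
   input injected *inside* the outer sigmoid; the z-update sums three
   separately squashed drive terms, all scaled by $\gamma\tau$. This
   reading makes strong guarantees possible: $x$ stays in $[0,1]$ (convex
   blend of a point in $[0,1]$ and a sigmoid output), and
   $|z_t| \le \max(\|z_0\|_\infty,\, 3\tau)$ whenever $\|H\|_\infty \le 1$
   (three drive terms each bounded by 1). Both bounds are asserted over
   10,000-step random rollouts in the test suite. Each update lives in one
   function so an alternative reading is a one-line change.
2. **Dimensional repair.** The synapse-to-astrocyte term
   $H \odot \tanh(x x^\top)$ is $N_x \times N_x$ but must enter
   $\mathbb{R}^{N_z}$; with $N_z = N_x$ each astrocyte pools its row of
   synapses, normalized by $N_x$ so the term stays in $[-1,1]$
   (astrocytes integrate over many synapses). $N_z = N_x$ is enforced.
3. **Initialization.** All maps are i.i.d. uniform on $[-0.1, 0.1]$;
   $w$ starts sparse (10% nonzero), $x_0 = 0.5$ (the sigmoid midpoint),
   $z_0 = 0$. $\tau$ has no published value beyond $\tau < 1$; 0.5 is the
   default.

A direct consequence of the bounded reading, measured and reported here
because it shapes every training result below: with $\gamma = 0.01$ the
state can move at most ~1% per step, so over a 20-step episode the
network is a slowly drifting clock. Event-locked structure in $x$ and $z$
is therefore necessarily slow and small in amplitude at these settings.

# Training

Training is clipped-surrogate policy optimization with generalized
advantage estimation. Reference settings: Adam at learning rate 0.001 for
every learnable matrix, clip 0.2, entropy coefficient 0.05, rollout
horizon 64 steps (spanning episode boundaries), 16 epochs per update,
minibatch 64, 10,000 episodes, success and return tracked as trailing
100-episode moving averages. Quantities the source does not state are
standard defaults, all exposed in `train_config()`: discount 0.99, GAE
$\lambda$ 0.95, value-loss weight 0.5, global gradient-norm clip 0.5,
advantage normalization per update.

Gradients flow through the recurrent dynamics by backpropagation through
time, implemented in C++ (RcppArmadillo) together with the forward
dynamics; the analytic gradients are verified against central differences
for all three architectures in the test suite. Minibatches are contiguous
segments of the rollout that replay dynamics from stored segment-start
states (with the defaults, one segment = the whole rollout); adjoints are
truncated at episode and segment boundaries. The dynamical state resets
at each episode start. One environment instance is used (no parallel
envs) so a single seed makes runs bit-identical: the seed drives delay
draws, parameter initialization, action sampling, and minibatch
shuffling.

The vanilla RNN ($h' = \tanh(W_h h + W_{in} o + b)$) and LSTM baselines
use hidden dimension 128 and share the environment, advantage, and update
code paths; policy and value read the same hidden state (the baselines
have no actor/critic anatomical split — an asymmetry inherent to the
comparison). Note that an LSTM at hidden 128 necessarily has about four
times the recurrent parameters of the vRNN at the same width;
`parameter_count()` reports the exact numbers.

**What training measures at desk scale.** At the reference network scale
with a reduced budget of 2,000-3,000 episodes (the scale used by the
test suite and the acceptance script; a full 10,000-episode run takes a
few minutes on one CPU), the neuron-astrocyte agent improves slowly and
noisily: 100-episode moving success oscillates around a gentle upward
trend (roughly 0.2 to 0.4-0.5 over 10,000 episodes in our runs), while
the LSTM baseline reaches ~0.8+ within 2,000 episodes. This is the
expected signature of the "weak clock" noted above: the policy must read
a sub-percent drift of the state, so the readout weights must grow large
before behavior differentiates in time. The comparative and
learning-progress checks in the acceptance suite are therefore honest
measurements of this implementation, not guaranteed outcomes; the
emergence analyses below are robust across the agents we trained.

# Analysis of internal dynamics

`record_rollouts()` runs the trained policy in a fixed environment
configuration until a requested number of successful trials is recorded
(with an attempt cap), storing the full per-step state, phase label,
action, and event labels. `pca_project()` centers activity and computes
an SVD basis; components are oriented so the largest-magnitude loading is
positive (a reproducible sign convention), and a stored basis can be
reused so single trials are projected into a shared multi-trial basis.
`align_to_event()` builds trials-by-time windows with time 0 at the event
step; samples outside the event's own trial are marked missing, never
zero-filled.

`pre_post_compare()` quantifies training-induced reshaping as the
event-locked amplitude of the astrocytic PC1: the maximal deflection of
the trial-averaged aligned trace within the post-event window from the
pre-event baseline mean. (The deflection form is used because a signed
"peak minus baseline" is ill-posed when the baseline is negative.) In our
trained-versus-untrained comparisons this amplitude grows by roughly an
order of magnitude with training. `unit_profiles()` z-scores each
astrocytic unit over the whole recording (the photometry convention),
aligns to an event, and classifies each unit's mean trace with the same
slow-signal rule used for photometry — trained networks show a mixture of
peak-like, trough-like, and state-change-like units.

# Photometry pipeline

The measurement side implements the defined trace computations for
two-channel (signal + isosbestic) recordings:

* `bleach_correct()` fits $a e^{-t/\tau_b} + c$ by least squares and
  divides the trace by the fitted curve — a multiplicative detrend,
  because bleaching scales fluorescence. Near-constant channels take the
  $a \to 0$ branch unchanged; fits whose curve leaves the data's own
  scale are rejected in favor of the identity correction with a warning.
* `dff()` computes $\Delta F/F = (F_{sig} - F_{iso})/F_{iso}$ pointwise
  and refuses near-zero isosbestic samples by index.
* `zscore_trace()` supports whole-trace, window (e.g. the 0-200 s session
  baseline), and per-event baselines (subtract the local $-2..+2$ s mean
  before session-level scaling).
* `lowpass()` is a second-order Butterworth applied forward and backward
  (zero phase) at 0.3 Hz by default; because `signal::filtfilt` applies
  zero initial conditions, the trace is odd-reflection padded by
  $6/f_c$ seconds so edges settle.
* `classify_slow_signal()` implements the trough / state-change / peak
  rule: within $-1..+1$ s of licking onset, find local extrema whose
  topographic prominence is at least `prominence_z` (default 1.0 — the
  source says only "clear/prominent", so the threshold is an explicit
  parameter); the qualifying extremum of largest magnitude decides the
  class by sign, and a trace with none — e.g. a smooth polarity
  reversal — is a state-change signal. Classification is run on the
  0.3 Hz low-passed trace (the slow-oscillation convention); this
  matters at realistic noise, where broadband fluctuations would
  otherwise produce spurious prominent extrema.
* `epoch_slopes()` fits least-squares lines over the pre-reward
  ($-4..0$ s), reward ($0..4$ s), and post-reward ($4..8$ s) epochs.
* `fast_transient_amplitude()` is the post-event maximum in $(0, +1]$ s
  minus the pre-event mean in $[-1, 0)$ s, per occurrence.
* `composite_sum()` adds the mean peak-class and trough-class traces and
  reports the Spearman rank correlation against a reference (typically
  the mean state-change trace) — the population-integration property.

# The synthetic generator

`generate_traces()` emulates what the analysis needs to be validated
against, not the acquisition chain: a session of `n_trials` trials
(default 20, 24 s each, events at fixed offsets: trigger entry/exit,
reward-zone entry/exit, reward onset, lick onset), a planted slow-class
waveform around each lick onset, optional fast exponential-decay
transients at chosen events, exponential photobleaching applied
multiplicatively to both channels, and independent Gaussian noise per
channel; the isosbestic channel carries bleaching and noise but no
signal. Sampling is 20 Hz — post-demodulation rates are
hardware-dependent and irrelevant to the arithmetic; 20 Hz keeps
simulations fast while satisfying the Nyquist margin for the 0.3 Hz
filter.

Template design: the peak class is a gaussian ($\sigma = 1.5$ s) centered
0.5 s before onset with a shallow dip after the reward window; the trough
class is its mirror with a late positive rebound; the state-change class
is *defined as the exact peak + trough mixture*, which yields a smooth
polarity reversal across the onset whose transition extrema fall near
$\pm 1.7$ s — outside the classification window — plus a second reversal
after the reward epoch. Defining state-change as the mixture makes the
composite property exact at the population level by construction, so the
round-trip test (generated peak + trough populations vs. the state-change
reference, Spearman $\ge 0.8$) probes the pipeline's noise robustness
rather than a lucky template choice.

What the generator does not emulate — and hence what passing round-trips
do not show about real data: motion artifacts and hemodynamic
contamination of the isosbestic channel, non-exponential (multi-component)
bleaching, sensor nonlinearity, trial-to-trial amplitude and latency
variability of the biological waveforms, and correlated noise. Recovery
rates on synthetic data are upper bounds on real-data performance.

# Numerical and reproducibility notes

* Degenerate inputs are contracts, not accidents: zero-variance activity
  yields a defined degenerate projection with a warning; absent events
  yield empty aligned tensors with a warning; stepping a terminated
  episode and mismatched grids are usage errors.
* Parameter archives are JSON with 17 significant digits, which
  round-trips IEEE doubles exactly; `load_network(save_network(p))`
  restores bit-identical matrices.
* Every `run_experiment()` command writes a manifest (command, full
  config, seed, package version, artifact MD5 digests);
  `rerun_from_manifest()` reproduces artifacts digest-for-digest.
* Problem sizes in the shipped tests and acceptance script: training runs
  use 2,500 episodes (three seeds per architecture), recordings use 10
  successful trials, and photometry round-trips use 300 planted sessions
  (100 per class) of 12 trials each — sizes chosen so a complete
  validation pass stays within a desk-scale compute budget while leaving
  the statistical assertions well-powered.

# Known limitations

* The update-rule parenthesization is one consistent reading of an
  ambiguously printed system; the bounded reading adopted here guarantees
  the stability invariants but caps the speed of internal dynamics at
  $\gamma$ per step, which slows policy learning at the reference
  $\gamma = 0.01$ and keeps astrocytic transients slow (see Training).
* The critic reads only astrocytic units and the actor only neuronal
  units; no biophysical calcium kinetics, spiking, or spatial astrocyte
  territories are modelled.
* Baseline value heads share the recurrent hidden state (no separate
  critic network); whether the original comparison did the same is not
  stated.
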