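---
title: "Multi-scale neuron-astrocyte networks: dynamics, meta-plasticity and context-dependent bandit learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale neuron-astrocyte networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliabandit)
```

## The model

Astrocytes envelop synapses (the tripartite synapse) and modulate synaptic
plasticity on time scales of seconds to minutes, orders of magnitude slower
than neuronal firing. `gliabandit` implements a rate-based model of this
interaction. Neurons carry a mean membrane potential $x_i$, synapses a
signed efficacy $w_{ij}$, astrocytes a graded calcium-activity surrogate
$z_k$:

$$\tau_n \dot x_i = -a_i x_i + \sum_j w_{ij}\,\phi(x_j) + u_i$$
$$\tau_w \dot w_{ij} = -b_{ij} w_{ij} + c_{ij}\,\phi(x_i)\phi(x_j) + d_{ij}\,\psi(z_k)$$
$$\tau_a \dot z_k = -e_k z_k + \sum_l f_{kl}\,\psi(z_l) + h_k\,\phi(x_i)\phi(x_j) + v_k$$

with $\phi$ the logistic sigmoid (firing-rate surrogate in $[0,1]$) and
$\psi = \tanh$ (graded astrocyte output in $[-1,1]$). The Hebbian gain
$c_{ij}$ may be negative (anti-Hebbian); the $d_{ij}\psi(z_k)$ term is the
astrocytic *meta-plasticity* pathway — the astrocyte reshapes how the
synapse evolves — and $h_k$ closes the loop by letting the astrocyte sense
the firing correlation of its monitored synapse. $v_k$ carries exogenous
contextual signals. Time constants obey $\tau_n \le \tau_w \ll \tau_a$;
with the reference values the astrocyte is two orders of magnitude slower
than the neurons.

We use one consistent activation set ($\phi$ = sigmoid, $\psi$ = tanh, and
a sigmoid $S$ in the bandit schedules) everywhere, including the motif
analysis: a single nonlinearity set keeps the dynamical analysis and the
learning experiments directly comparable.

### The two-neuron / one-astrocyte motif

The smallest interesting instance is a reciprocal excitatory–inhibitory
neuron pair with both synapses enveloped by one astrocyte
(`motif_params()`, five ODEs). The packaged default parameterisation
(`a1 = 0.7, a2 = 0.6, b1 = 1.6, b2 = 1.7, c1 = 12, c2 = -10, d1 = -4,
d2 = 5, eps = 0.6, h = 6, tau1 = tau2 = 0.01, tau3 = 1`) is bistable:
three equilibria, two stable and one saddle.

```{r fixed-points}
eq <- find_fixed_points(motif_params(), n_starts = 150)
glance(eq)
```

### Singular perturbation and the pseudo-bifurcation

Because $z$ is slow, the fast neuron–synapse subsystem effectively sees a
*frozen* astrocyte output $\theta = \psi(z) \in [-1, 1]$ and can be studied
as a four-ODE system parameterised by $\theta$
(`reduced_fixed_points()`). Sweeping $\theta$
(`bifurcation_sweep()`) reveals a saddle-node fold: one equilibrium
branch exists over the whole range, and a stable/saddle pair is created as
$\theta$ grows. The slow astrocyte variable thus acts as a
pseudo-bifurcation parameter that switches the fast subsystem between
mono- and multi-stable regimes — the dynamical mechanism behind
context-guided meta-plasticity.

We interpret the frozen axis as the astrocyte *output* $\psi(z)$, not $z$
itself, which keeps it in the bounded interval $[-1, 1]$.

## Numerical choices

* **Fixed points** are found by damped-Newton iteration with the analytic
  Jacobian, multistarted from a deterministic Halton grid over
  $[-3, 3]$ for $x$ and $z$ and $[-20, 20]$ for $w$ (synaptic equilibria
  scale as $|c|/b \approx 7.5$ here). Roots are accepted at residual
  $10^{-8}$ (max-norm) and deduplicated at $10^{-6}$. Newton may leave the
  start box, which is intended: starts only need to be in the basin.
* **Stability** is classified from the Jacobian spectrum with a
  $\pm 10^{-8}$ band on real parts; eigenvalues inside the band yield
  `nonhyperbolic`, which is reported, never coerced.
* **Folds** are localised by bisection on $\theta$ between grid points
  whose equilibrium count differs, to a width of $10^{-4}$. Branches are
  linked across the grid greedily by proximity in $x_1$. No
  pseudo-arclength continuation is attempted: the only qualitative event in
  range is the fold.
* **Integration** uses fixed-step classical Runge–Kutta-4 with default
  `dt = tau_min / 20` (a warning fires above `tau_min / 10`). Fixed steps
  make trajectories bit-reproducible; the slow–fast system is non-stiff at
  these parameter scales. An adaptive reference integrator (deSolve's
  `lsoda`) serves as an independent cross-check in the test suite. Ensemble
  basin experiments integrate all initial conditions as matrix columns in
  one pass.

## The discrete-time trainable network

Setting all self-decays to one, taking $\tau_n = \tau_w = \tau$ and
$\tau_a = 1$, and discretising by first-order Euler with step $\gamma$
gives the agent update used one step per bandit trial
(`init_agent()`/`agent_step()`):

$$x_t = (1-\gamma)x_{t-1} + \gamma\,(W_{t-1}\phi(x_{t-1}) + W_{in1} I_t)$$
$$W_t = (1-\gamma)W_{t-1} + \gamma\,(C \circ \Phi(x_{t-1}) + D\,\psi(z_{t-1}))$$
$$z_t = (1-\gamma\tau)z_{t-1} + \gamma\tau\,(F\psi(z_{t-1}) + H\Phi(x_{t-1}) + W_{in2} I_t)$$
$$y_t = W_{out}\,x_t + b_{out}$$

$\Phi(x)$ is the full flattened $n^2$ outer product
$[\phi(x_i)\phi(x_j)]$ (diagonal included), and $C$ is elementwise — one
Hebbian gain per synapse. The continuous model instead indexes an explicit
ordered-pair synapse list without self-pairs; both conventions are
documented and tested against each other where they overlap. Defaults are
$\gamma = 0.1$, $\tau = 0.01$ (so the astrocyte layer relaxes over
$1/(\gamma\tau) = 1000$ trials), 128 neurons and 64 astrocytes at full
scale. The dynamic state starts at zero: $W$ is *state*, grown by the
plasticity rule, not a trained parameter.

**Initialisation.** $C, D, F, H \sim \mathcal N(0, 1)/\sqrt{N}$ and
$W_{in1}, W_{in2}, W_{out}, b_{out} \sim \mathcal U(\pm 1/\sqrt{N})$, with
$N$ the fan-in (input dimension) of each map — the variance-preserving
reading of $1/\sqrt{N}$ scaling. For the elementwise vector $C$ we read it
as a diagonal map on the $n^2$-dimensional correlation vector, so its
fan-in is $n^2$ (sd $1/n$). This choice matters: with $O(1)$ Hebbian
gains the dynamic weights and then $x_t$ grow to order tens, the softmax
readout saturates irreversibly (see below) and learning collapses.

## Bandit tasks and the training loop

Three-armed Bernoulli bandits (`bandit_spec()`):

* **stationary** — means $(0.4, 0.8, 0.1)$; cue constantly 1.
* **flip-flop** — arm 2 alternates between $0.92$ and $0.042$ every
  `switch_period` trials; the other arms keep the stationary values 0.4 and
  0.1, so the identity of the best arm flips at every switch. Cue $-1$
  in even phases, $+1$ in odd ones, flipping exactly when the mean flips.
* **smooth** — $\mu_i(t) = \mu_i^* S(Q \sin(2\pi t/P + 2\pi i/n))$ with
  $P = 10^4$, $Q = 100$ and $\mu_i^* = 0.9$ for all arms (equal
  amplitudes make every arm periodically optimal). Cue encodes the
  currently-best arm on $\{-1, 0, 1\}$.

Trials are 1-indexed. Rewards are Bernoulli draws at the scheduled means;
performance is cumulative pseudo-regret
$R_T = \sum_t (\max_i \mu_i(t) - \mu_{a_t}(t))$, computed from schedule
means rather than realised rewards.

Training (`train_run()`) is trial-wise REINFORCE: softmax policy over the
readout (`policy_from_logits()`), one sampled action, one Bernoulli
reward, the loss $L_t = (\bar r_t - r_t)\log p_t^{a_t}$ with $\bar r_t$
the running mean of rewards up to and including trial $t$, one Adam step
(learning rate $10^{-3}$, standard moment defaults) per trial. All
randomness flows through R's global RNG, so a single seed reproduces a run
bitwise. The same loop trains the stacked two-layer vRNN/LSTM/GRU
baselines (cue into layer 1, layer 1 output through a trained matrix into
layer 2), and runs the UCB1/Thompson/DUCB/SWUCB index policies, which need
no gradients; the trainer dispatches through one generic interface, so the
environment/loss/optimizer path is identical across agents by
construction.

### Gradient truncation, and why the default window is one trial

Gradients are computed analytically (verified against central finite
differences for every agent kind) by backpropagation through a cached
window of recent steps. The default window is **one trial**: the state
carried into the current trial is treated as a constant, so the gradient
reaches $W_{out}, b_{out}$ and $W_{in1}$, while the plasticity and
astrocyte matrices $C, D, F, H, W_{in2}$ keep their initial values and act
as a fixed, context-modulated reservoir: the slow $z_t$ integrates the cue
stream through $W_{in2}$ and reshapes the fast weights through
$D\psi(z_t)$ regardless of training.

A longer window (`bptt_window`) is implemented and exercised in the tests,
but it is not the default for a reason worth recording. With per-trial
REINFORCE the windowed gradients of $H$ and $D$ are sign-coherent along
whole rows (they are outer products with the non-negative correlation
vector $\Phi$), and Adam's normalised updates then march these rows
coherently. The recurrent state inflates, the readout saturates
($p \to 1$ for one action), and the policy gradient
$\propto (1 - p)$ falls below Adam's $\epsilon$ floor: the agent freezes on
one arm and cannot recover after a context switch. At our scales the
one-trial window avoids this failure mode entirely and reproduces the
qualitative phenomenon of interest; the windowed path remains available
for experimentation.

## What the experiments show at desk scale

The packaged experiment drivers run at reduced size — $n = 32$, $m = 16$
for the agent, 32 units per layer for the baselines, horizons of 5000
(stationary), 15000 with a 2500-trial phase (flip-flop ablation) and 10000
(ratio sweep) — chosen so the full battery completes in minutes on one
core while preserving every qualitative contrast:

* stationary: the neuron-astrocyte agent reaches a final-window regret
  rate far below the analytic uniform-play rate $0.3667$/trial, like the
  trained recurrent baselines and the index policies;
* flip-flop: with $\tau = 0.01$ the post-switch regret slope collapses
  (more than five-fold below the pre-learning slope after two full context
  cycles) — the agent has associated each cue with its policy and switches
  without re-learning. The $\tau = 1$ variant (identical parameter count)
  keeps paying a fresh cost after every switch, and the vRNN/LSTM
  baselines re-learn from scratch each phase, accumulating an order of
  magnitude more regret: the catastrophic-forgetting signature;
* ratio sweep: `ratio_sweep()` trains agents at fixed $n$ across
  astrocyte:neuron ratios and reports mean asymptotic regret per ratio.
  The expectation is an interior optimum on the flip-flop task —
  both very few and very many astrocytes hurting — but at desk scale the
  between-ratio differences are comparable to seed noise, so this sweep
  should be read as machinery for a larger-scale experiment rather than a
  settled desk-scale result.

`pca_projection()` reproduces the population-level view: projected onto
principal axes, astrocyte activity separates the two contexts and the sign
of its second component flips between them.

## What the synthetic environments do and do not emulate

The bandit generator reproduces the reward statistics and cue streams of
the study conditions exactly (Bernoulli draws, abrupt and smooth mean
schedules, scalar cues). It does not emulate reward delays, cue noise, or
any sensory front end: the cue is a clean scalar. Passing tests therefore
demonstrate the dynamical and learning mechanisms, not robustness to noisy
or ambiguous context signals. Desk-scale sizes also soften some
full-scale contrasts: in particular, at $n = 32$ the $\tau = 1$ variant
still learns each phase tolerably well through the direct cue pathway, so
its failure shows up as a persistent per-switch cost rather than outright
divergence; and the within-context variance ordering between the synaptic
and astrocytic projections is not a reliable desk-scale effect and is
reported, not asserted.

## Degenerate inputs and edge cases

Single-neuron and single-astrocyte networks are permitted (and used in the
unit tests); a network with no synapses is rejected. Non-finite states
abort integration and agent steps with the offending component named. A
policy probability of zero is clamped to $10^{-12}$ with a warning inside
the loss. Ties in every argmax (index policies, best-arm labelling) break
toward the lowest index, deterministically.
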