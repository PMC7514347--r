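---
title: "Models and methods in critmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in critmem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(critmem)
```

`critmem` studies a single scientific question from two sides: does the
vicinity of a dynamical critical point give a neuronal network the
susceptibility it needs to absorb a new, weakly impinged memory, and does
successful consolidation then push the dynamics into a sub-critical, more
stable regime? The first side is an attractor-network simulation; the second
is a branching-parameter analysis of (here: synthetic) spike trains. This
vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic data can and cannot show.

## The attractor network

Neurons are binary, `S_i = +1` (firing) or `-1` (quiescent), on a directed
small-world graph of `N` nodes in which every neuron receives exactly `k`
edges. The local field is the in-degree-normalised weighted input

    h_i = (1/k) * sum_{j -> i} J_ij S_j

and all non-clamped neurons update synchronously by a heat-bath rule: align
with `sign(h_i)` with probability `P = 1 / (1 + exp(-2 |h_i| / T))`,
anti-align otherwise. `T` is the control parameter; `P -> 1/2` as `T -> Inf`
(disorder) and `P -> 1` as `T -> 0` (deterministic alignment, which is the
ordered regime that recall requires). `sign(0)` is taken to be the neuron's
current sign, so a zero-field neuron keeps or flips with probability 1/2
each. A deterministic "keep" at zero field would freeze the non-negligible
fraction of neurons whose incoming `+/-1` weights cancel exactly (about 17%
at `p = 1, k = 20`) and would visibly depress the disordered-regime flip
fraction below its `~N/2` value; a zero field carries no information, so the
unbiased coin is the defensible choice.

`p` native memories — i.i.d. random `+/-1` patterns — are embedded by the
outer-product rule `J_ij = (1/p) sum_mu xi_i,mu xi_j,mu` on the existing
edges only (`J_ii = 0`). Note the `1/p` normalisation: the temperature scale
of the ordered phase shrinks roughly like `1/p`, which is why the critical
line of the loading--temperature diagram declines as memories are added.

The topology is a directed Watts--Strogatz variant: a ring lattice where
each node receives from its `k` nearest neighbours (for odd `k`,
`ceiling(k/2)` clockwise), then each incoming edge's *source* is rewired
with probability 0.1 to a uniform non-self, non-duplicate source. Rewiring
the source preserves every in-degree exactly, which the `1/k` normalisation
of the field presumes. Whether rewiring preserves in- or out-degree is a
genuinely open choice; group statistics of the input-connectivity analysis
depend on it only weakly.

### External input

A new random configuration `xi^e` reaches the network through a randomly
chosen subset `N'` of neurons whose states are clamped to `xi^e` and whose
*outgoing* existing edges are overwritten with `J_ij = (w_e/p) xi^e_i
xi^e_j`. No edges are created: the input modifies the backbone that is
already there. Alternatively a global persistent field `(w_ext/p) xi^e_i`
can be applied to every neuron with no clamping.

### Plasticity

Learning is the unbounded state-based Hebbian rule `J_ij += eps S_i S_j`
applied after each dynamics step, with `eps = 0.1` as reference rate. Edges
*targeting* clamped neurons are frozen (those neurons receive no relevant
input); edges *sourced* at clamped neurons are plastic, because their output
drives the rest of the network. The opposite convention is available behind
`update_input_edges = FALSE` for sensitivity checks; at the operating points
used here it changes only the small `N'`-adjacent fraction of weights.

### Order parameters and the critical temperature

Two order parameters are recorded: the overlap `m = |mean(xi_i S_i)|` over
non-clamped neurons (per native memory and for `xi^e`), and the stability
curve — the fraction of non-clamped neurons that change state per iteration,
which is ~0 in the ordered regime and ~1/2 in the disordered one. The
critical temperature is the half-maximum point of an order-parameter curve,
found by linear interpolation between grid points, or by a least-squares
fit of `f(T) = 0.5 / (1 + exp(-(T - T_c)/mu))` to the flip curve
(`fit_sigmoid_stability()`, with a half-max fallback on non-convergence).
Half of the *observed* maximum is used rather than half of the theoretical
ceiling so the estimator stays meaningful when low-temperature recall is
imperfect at high loading. Flip counts are reported as fractions of
non-clamped neurons so the sigmoid's 0.5 asymptote is dimensionless.

### Protocol structure and defaults

All experiments are phase protocols: a plasticity-off relaxation (`pre`),
an interleaved dynamics + Hebbian phase (`learn`), and a plasticity-off
relaxation (`post`; input still wired, or field switched off for the
global-field map). Defaults are `pre = 100`, `learn = 500`, `post = 100`
iterations with final-state quantities averaged over the last 10 iterations
to suppress single-step noise; couplings are reset between temperatures.
One hundred relaxation iterations are enough for the overlap to plateau at
the sizes used here except very near the transition, where critical slowing
widens the apparent transition — one reason the desk-scale critical
temperature reads slightly below the mean-field value of 1.

Two protocol-level choices deserve emphasis:

* **Consolidation-time clock.** `consolidation_time()` relaxes the system
  without plasticity before starting the learning clock. Without that, the
  very first synchronous step from a random initial state aligns a large
  fraction of the network with `xi^e` (the native contribution to the field
  is still incoherent), which would absurdly report one-step consolidation
  even deep in the sub-critical regime.

* **Stability-shift experiment.** For the learning-rate sweep the learning
  phase is shortened to 100 iterations and the temperature grid widened to
  [0.2, 5]. The unbounded rule grows couplings roughly linearly in
  `eps * iterations`, so the post-learning transition moves far to the
  right; the shorter phase keeps it inside a grid that can still be swept
  at desk scale while preserving the approximately linear dependence of the
  shift on `eps`.

### Desk-scale sizes and finite-size choices

The reference system (`N = 10000`, 2% connectivity, `|N'| = 700`) is too
large for routine testing, so the package's experiments run at `N = 1000`.
Downscaling every parameter proportionally is *not* faithful: with
`k = 20` and `|N'| = 70`, each neuron would receive on average only 1.4
input edges (Poisson), so a quarter of the network would get no direct
input at all — the mean input field would match the reference but its
heterogeneity would not, and consolidation becomes weak and displaced to
higher temperatures. The consolidation experiments therefore use `k = 200`
at `N = 1000`, which preserves the reference value of `k |N'| / N = 14`
input edges per neuron (and the mean input field `~0.21 w_e / 3`). The
critical-temperature and quiescence checks, which do not involve input,
keep the 2% convention (`k = 20`); the transition point is insensitive to
this choice.

The zero-temperature capacity check is its own special case: couplings are
fully connected, and relaxation uses *sequential* deterministic sign
updates, which descend the energy to a fixed point. Fully parallel
deterministic updates admit period-2 cycles on symmetric couplings and can
spuriously destroy recall. A loading passes only if **every** stored
pattern keeps overlap at least 0.9, and the largest passing `p` is found by
bisection at resolution `max(1, N/200)`. The strict all-patterns criterion
binds on the worst of `p` draws, which at `N = 500` biases the estimate a
little below the thermodynamic limit of about 0.138 — the package reports
about 0.115--0.12, consistent with that limit at this size.

Stability classification across the phase maps uses a single threshold,
`m >= 0.45`, everywhere (the global-field map, the capacity diagram's
native-stability line and consolidation region), so all "stable" claims are
directly comparable.

## Branching-parameter analysis of spike trains

The spike-train half asks whether pooled population activity behaves like a
(possibly subsampled) driven branching process with ratio `sigma`:
`sigma = 1` is critical, `sigma < 1` sub-critical. Activity is pooled
across units and binned into 16 ms half-open bins anchored at each
slow-wave-sleep bout start (partial final bin discarded; bouts shorter than
100 bins are refused by default because the estimate is unreliable).

For lags `k = 1..k_max` (default 40, i.e. 640 ms) the regression slope
`r_k = Cov(a_t, a_(t+k)) / Var(a_t)` is computed, and `r_k = b sigma^k + c`
is fitted by least squares. The point of the multistep (multi-lag) design
is subsampling invariance: observing only a fraction `q` of events scales
every `r_k` by the same factor, which the amplitude `b` absorbs, so `sigma`
is recovered even though the naive single-lag slope `r_1` collapses. The
constant offset `c` absorbs slow additive drifts and is reported with the
fit. Starting values come from a log-linear fit of the positive slopes,
which also serves as the fallback when the nonlinear fit fails.

Bouts are screened for non-stationarity before averaging; a bout is
rejected when (a) its two halves' mean rates differ by more than 0.5 pooled
standard deviations (drifting drive), (b) the exponential fit explains less
than 70% of the lag-slope variance (structure inconsistent with a single
branching ratio — fast up/down-state switching lands here because it makes
the lag slopes oscillate), or (c) the fitted `sigma` reaches 1.1 (runaway).
These three thresholds are this package's explicit stand-in for the
consistency checks of the reference estimation method, whose exact criteria
are not published; they are configurable and logged per bout, and no claim
of equivalence is made. Near-critical bouts occasionally trip the drift
screen by chance — that is by design, the cost of a conservative screen.

Per subject, accepted per-bout estimates are averaged within each epoch
(baseline vs post-conditioning) with standard errors; the group summary
reports each condition's mean change and a one-sample t test of
`delta sigma < 0`, for context only — no gating, no outlier removal. The
behavioural learning score is the percentage-point change in freezing
between test and pre-shock baseline.

## The synthetic cohort

`make_cohort()` generates everything the pipeline reads: per-subject,
per-epoch spike and bout files, a manifest, and a behaviour table. The
generative model is deliberately the estimator's own model class — a driven
Poisson branching process, binomially subsampled, scattered into spike
times uniformly within bins and multinomially across units — so that
parameter recovery is a well-posed check of the estimator, not of the
model. Defaults emulate the study design the pipeline targets: 5
conditioned (CFC) and 3 sham subjects, two epochs, 10 bouts per epoch with
log-uniform 2--10 minute durations (typical slow-wave-sleep bout
variability), 15 units, 10% subsampling, and an observed pooled rate of
about 25 spikes/s. Baseline branching ratio is 0.99 for both groups — near
critical but stationary; an *exactly* critical driven process has a
linearly growing mean, is non-stationary by construction, and is correctly
rejected by the screen, so "sigma = 1.00" is representable only as a limit,
not as a usable baseline. Post-conditioning ratios drop by 0.05 (CFC) and
0.01 (Sham), and conditioned subjects draw higher learning scores.

What passing on this synthetic cohort shows: the binning, estimation,
screening, aggregation and reporting layers recover known parameters and
their group-level sign pattern end to end. What it does not show: anything
about real CA1 spike trains, which have refractoriness, unit-rate
heterogeneity, oscillatory modulation and sleep-stage boundary effects that
the generator intentionally omits.

## Reproducibility

All randomness flows through explicit integer seeds; protocols derive
per-realization seeds as `seed + r`, and identical parameters plus seed
reproduce results (and cohort files) byte for byte. `scripts/acceptance.R`
recomputes the package's three headline desk-scale numbers — the
single-memory critical temperature, the zero-temperature capacity, and the
deep-sub-critical flip count — from scratch at `N = 1000` / `N = 500`.
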