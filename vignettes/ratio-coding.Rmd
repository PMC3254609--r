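---
title: "Ratiometric blend coding in a model macroglomerular complex"
author: "mgcratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric blend coding in a model macroglomerular complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Male moths locate females by flying up a pheromone plume, and what
identifies the right female is not a single compound but the *ratio* of the
blend components.  The macroglomerular complex (MGC) of the antennal lobe is
the dedicated circuit for this task: each pheromone component drives one
receptor channel, each channel feeds one glomerulus, and the projection
neurons (PNs) of the two glomeruli broadcast a population code to higher
brain centres.  `mgcratio` implements a small firing-rate model of this
circuit and the complete analysis suite needed to ask a precise question:
how well does the PN population code report the blend ratio, and what
happens to that code when the stimulus itself fluctuates the way a real
plume does?

## The model

Every neuron is a first-order firing-rate unit,

$$\tau_i \, \dot a_i = -a_i + f\!\Big(\sum_j w_{ij}\, a_j + I_i(t)\Big),$$

where $a_i \in [0,1]$ is the activation of neuron $i$, $w_{ij}$ the synaptic
weight from $j$ to $i$, and $I_i(t) = \mathbf{A}_i \cdot \mathbf{G}(t)$ the
afferent drive: the dot product of the neuron's two afferent weights with
the two-channel receptor input $\mathbf{G}(t)$.  During a pulse of a blend
with ratio $\rho$ and total concentration 1, $\mathbf{G} = (\rho, 1-\rho)$;
between pulses it is zero.  $f$ is a rectified sigmoid,
$f(x) = \tanh(g\,x)$ for $x > 0$ and $0$ otherwise, so the resting state is
exactly zero and activity is bounded in $[0, 1)$.  Time constants are 10 ms
for the 30 PNs and 20 ms for the 30 inhibitory local neurons (LNs).

The network (60 neurons) is wired by fixed random rules.  All weights are
drawn from normal distributions and sign-rectified (excitatory draws below
zero, and inhibitory draws above zero, are set to 0):

| connection | probability | weight (mean ± sd) |
|---|---|---|
| ORN channel → its PNs (one channel per PN) | 1 | 1 ± 1 |
| ORN channels → LNs (both channels) | 1 | 1 ± 1 |
| PN → PN, within glomerulus only | 0.8 | 0.0125 ± 0.1 |
| PN → LN | 0.5 | 0.033 ± 0.1 |
| LN → PN | 0.2 | −2.5 ± 0.1 |
| LN → LN, FPA regime | 1 (all-to-all) | −15 ± 0.1 |
| LN → LN, LCA regime | 0.25 (asymmetric) | −15 ± 0.1 |

The two regimes differ *only* in the LN-to-LN wiring, and `build_network()`
draws that block last so that FPA and LCA networks built from the same seed
share every other block (a property the test suite checks).  With all-to-all
symmetric inhibition (FPA, fixed-point attractor) the LNs compete
winner-takes-all: after a brief transient a single LN remains active and the
PN spatial pattern freezes.  With sparse asymmetric inhibition (LCA,
limit-cycle attractor) no LN coalition can suppress all others permanently;
the active subset keeps switching, dragging the PN pattern through a
ratio-specific spatiotemporal sequence.

Conventions fixed for reproducibility: weights are drawn block by block in a
documented order, row-major within each block; no neuron synapses onto
itself (an LN self-inhibition would act as adaptation and change the
competition mechanism, and the wiring rules describe competition *between*
cells); PNs 1–15 belong to channel 1 and PNs 16–30 to channel 2.

### The sigmoid and its gain

The squashing function's exact shape is a free choice of the model; any
bounded rectified sigmoid produces the two regimes.  We use rectified
$\tanh$ with gain $g = 2$ as the default.  The gain sets the operating
point, and the two decoding strategies respond to it in opposite ways.  At
low gain PN activity at the FPA attractor stays graded, so the frozen
spatial pattern retains fine ratio information and the FPA decoder performs
unrealistically well.  At high gain the attractor pattern saturates towards
a quasi-binary code determined by which LN won — the "limited number of
discrete attractors" operating regime — and FPA accuracy falls below LCA
accuracy, which is the characteristic contrast between the regimes; pushing
the gain further, however, makes the FPA transient itself brittle, and
pulse-train robustness and the timing statistics degrade.  Gain 2 is the
smallest value at which the FPA-below-LCA plateau ordering is robust across
network ensembles while the fixed-point regime keeps its other signatures
(single winner, stationary late pattern, flat specificity beyond 50 ms
code length).  It remains exposed as `sim_config(gain = )`.

## Integration and noise

The dynamics are integrated with classical fixed-step 4th-order Runge–Kutta
at 1 ms (in compiled code; `dt` is configurable).  The stimulus is held at
its value at the left endpoint of each step: pulse edges lie on the ms grid,
so no RK stage ever straddles a stimulus discontinuity and each step
integrates a smooth piece.  After each step, Gaussian noise
($\mu = 0$, $\sigma = 5\times10^{-4}$) is added to every activation —
state addition once per step rather than a derivative term, the natural
reading of per-time-step noise in a fixed-step scheme — and the state is
clipped to $[0,1]$, which keeps the boundedness invariant literal; with
this noise amplitude clipping is only ever active at the 0 boundary.
Initial activations are drawn from $\mathcal N(0.01, 0.0025)$; without
stimulation the network decays to the zero equilibrium within 100 ms, which
is why every stimulus program starts after a 100 ms settling period.

Three random streams are kept separately seedable — network construction,
initial conditions, per-step noise — so a network realization can be reused
across noise repeats.  All ensemble drivers derive child seeds from one
master seed with a Lehmer-style map (`derive_seed()`).

A caveat on step-size robustness: outside the onset transient, halving `dt`
changes activations by less than $10^{-3}$ (the suite checks this from
300 ms onward), but *during* the winner-race transient the competitive
dynamics amplify any perturbation exponentially, so pointwise agreement
through the transient is not attainable for any integrator — trajectories
separated by $10^{-15}$ at onset can differ visibly near the saddle points
before collapsing onto the same attractor.  Binned statistics and late
states are converged; individual transient samples are sensitive.

## Stimuli

`make_pulse_train()` produces square pulses at 1 ms resolution (no
rise-time model: plume filaments have sharp edges at this timescale and the
original analyses use square pulses).  The total concentration is held at 1
so the ratio alone parameterizes the blend.  `make_random_plume()` draws a
plume-like telegraph schedule: exponential silent gaps (default mean
200 ms) and pulse durations of at least 40 ms — the shortest filament
considered realistic — plus an exponential excess with the same mean.  The
law of the gaps is not constrained by anything we reproduce; any renewal
process respecting the 40 ms minimum serves, and the choice is exposed
through `mean_rate` and `min_pulse_ms`.

## Response representations

All analyses operate on the time-binned PN activity matrix
(`bin_responses()`, default $\Delta t = 10$ ms, left-closed bins): column
$j$ is the mean spatial pattern in bin $j$.  Binning conserves the mean of
the underlying trace, and a flattened *spatiotemporal vector*
(`flatten_response()`, PN-major order, invertible) truncated to a *code
length* measured from stimulus onset is the feature vector for decoding.
Pattern similarity is the Pearson correlation between spatial vectors;
all-silent bins (common before stimulus onset) have no defined correlation
and are mapped to 0 with a `degenerate` flag rather than raising an error,
because whole-trace maps legitimately include them.  Averaged maps are
arithmetic means of correlation coefficients (no Fisher-z transform — the
map values are read directly as correlations, matching how the original
maps are presented).

## The analyses

**Cross-correlation maps** (`correlation_map_experiment()`): responses to a
reference 500 ms pulse are correlated, bin against bin, with independently
simulated test responses (another 500 ms trial, or pulse trains of five
50 ms pulses with 10/50/100 ms gaps), averaged over random ratios and
networks.  FPA yields a block of high correlation over the whole stimulation
period; LCA concentrates correlation near the diagonal.

**Bin-wise classification** (`train_binwise()`,
`cross_classification_map()`): ratios drawn uniformly are grouped into five
classes centred at 0, 0.25, 0.5, 0.75, 1 (half-width 0.125, boundary ties
rounded half-up — a measure-zero convention).  For every training bin, a
decoder is fitted on the instantaneous patterns: PCA retaining ≥ 90% of
variance (this removes the linearly dependent dimensions that would make
the within-class covariance singular) followed by linear discriminant
analysis.  PCA loadings come from the training set only; test patterns are
projected with them.  If the within-class covariance is still singular the
fit degrades, with a warning, to a ridge-regularized discriminant;
all-silent training bins yield an explicitly *uninformative* classifier
whose predictions are seeded uniform draws, i.e. exact chance (20% for
balanced classes).  The map of accuracies over (training bin, test bin)
pairs visualizes when the code is stable (FPA: a block) versus switching
(LCA: a band).

**Code length analyses** (`accuracy_vs_code_length()`,
`specificity_curve()`): the same PCA+LDA recipe applied to flattened
spatiotemporal vectors truncated to increasing code lengths, 100 training /
400 test stimuli per network (the same split is used for the map and the
code-length curves).  Ratio specificity is summarized by the bell-curve
width $W(\rho)$: the second moment, about its peak, of the correlation
between the response to $\rho$ and responses on a dense ratio grid (step
0.025), taken over a ±0.25 window.  Near the boundaries the window is
one-sided ($\rho < 0.25$: only ratios above $\rho$; $\rho > 0.75$: only
below), so it never leaves $[0,1]$; the exact endpoints are exposed as
parameters.  Negative correlations are clipped to zero so they cannot act
as negative mass in the moment.

**Trajectory divergence timing** (`trajectory_distance_timing()`): per
network, responses to the five class-centre ratios (20 noise repeats each)
are binned at 5 ms and projected into a single 3-component PC space fitted
on all pooled patterns of that network; per-ratio mean trajectories are
repeat averages, and the statistic is the time after onset at which the
mean pairwise Euclidean distance between them peaks.  One PCA per network
(not per ratio) matches the single common axis space in which the
trajectories are compared; distances are between repeat-averaged
trajectories because the statistic is reported per network realization with
variability across realizations.  `compare_regime_timing()` is the Welch
t-test between regimes.

**Pulse-train interference** (`interval_interference_experiment()`): the
bin-wise decoder is trained on single 500 ms pulse responses and tested on
trains of five 50 ms pulses.  Each test pulse is scored at matched latency
against the first 50 ms of the long-pulse response, giving one accuracy per
pulse.  Gaps of 100 ms let every pulse restart the response and per-pulse
accuracy matches the single-pulse case; 50 ms gaps let the tail of one
response collide with the onset transient of the next, which selectively
degrades the LCA code — the central cost of using intrinsic dynamics as a
coding dimension under naturalistic stimulation.

**Long-run behaviour** (`detect_attractor()`): on multi-second simulations
the LCA dynamics eventually stop switching.  The detector classifies the
final second as a fixed point (every neuron's range below `tol`) or a
periodic orbit (the window matches itself under a time shift), and
estimates the settling time as the last excursion, in RMS across neurons,
beyond `tol` from the set of late states.  `tol` defaults to 0.05
activation units: an order of magnitude above the stationary noise floor
produced by the $5\times10^{-4}$ per-step noise, an order of magnitude
below switching excursions.  The late LCA state typically has half a dozen
LNs co-active, unlike the FPA's single winner.

## What the generators emulate — and what they do not

The synthetic networks and stimuli *are* the study system: there is no
external data.  The generator reproduces the circuit's connectivity
statistics, not any particular animal: real MGCs have more PNs per
glomerulus, heterogeneous time constants, receptor/ORN transduction
dynamics (omitted here by design), triphasic PN responses and offset
responses, none of which the model contains.  Passing tests therefore show
that the *wiring-pattern hypothesis* — symmetric versus asymmetric lateral
inhibition selecting spatial versus spatiotemporal codes — behaves as
described at this scale; they say nothing about quantitative rates in any
real preparation.

Two known quantitative deviations of this implementation are worth naming.
First, the off-diagonal baseline of the averaged LCA correlation map sits
near 0.6–0.75 rather than below 0.5: with LN→PN connection probability 0.2,
roughly a quarter of PNs are uninhibited at any moment and carry a static,
afferent-driven pattern component that keeps distant time bins positively
correlated.  The band *structure* (a sharp high-correlation core a few tens
of ms wide over an elevated baseline) is reproduced; the baseline level is
not.  Second, the settling time of 5-second LCA runs is strongly
realization-dependent (bimodal: many runs settle within ~0.4 s, a minority
switch for several seconds), so the "typical" settling time is sensitive to
the ensemble; the co-activity of multiple LNs at the late fixed point is
robust.

## Problem sizes

The test suite and the acceptance script run the experiments at their
natural scale — 20 network realizations per regime, 100 training and 400
test stimuli per network, 20 noise repeats for trajectory statistics,
5-second single runs for the long-duration checks — with smaller desk-scale
cases (3–5 networks, reduced test sets) for the property checks where the
full ensemble adds nothing.  A complete run of the decoding protocol for
both regimes is about ten minutes on one CPU; everything else is seconds to
a couple of minutes.
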