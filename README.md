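# mgcratio

Ratiometric blend coding in a firing-rate model of the insect antennal-lobe
macroglomerular complex (MGC).

Male moths identify a conspecific female by the *ratio* of her pheromone
blend components, and they must read that ratio out of a plume that flickers
on and off at tens of milliseconds.  The MGC — two glomeruli, each driven by
one receptor channel — is the circuit that solves this.  `mgcratio`
implements a 60-neuron firing-rate model of that circuit (30 projection
neurons, PNs, and 30 inhibitory local neurons, LNs) together with the full
analysis suite for asking how well the PN population output encodes the
blend ratio ρ ∈ [0, 1], and what stimulus dynamics do to that code.

Every neuron follows

  τᵢ ȧᵢ = −aᵢ + f( Σⱼ wᵢⱼ aⱼ + **A**ᵢ·**G**(t) ),

with activations aᵢ ∈ [0, 1], a rectified-tanh squashing function f, time
constants of 10 ms (PNs) and 20 ms (LNs), Gaussian state noise per 1 ms
Runge–Kutta step, and a two-channel input **G** = (ρ, 1−ρ) during odour
pulses.  Random wiring follows fixed biological rules; the single structural
switch is the LN-to-LN inhibition:

* **FPA** (fixed-point attractor): all-to-all symmetric inhibition →
  winner-takes-all; one LN wins, the PN spatial pattern freezes — a spatial
  code.
* **LCA** (limit-cycle attractor): sparse (p = 0.25) asymmetric inhibition →
  no permanent winner; active LN coalitions keep switching, producing
  ratio-specific PN *spatiotemporal* sequences — a temporal code.

The analyses quantify the trade-off between these codes: bin-wise
PCA + linear-discriminant classification of five ratio classes,
cross-correlation and cross-classification maps over time-bin pairs,
ratio-specificity bell-curve widths versus code length, decoding accuracy
versus code length, 3-PC trajectory divergence timing, pulse-train
interference, and long-run attractor detection.

## Worked example

```r
library(mgcratio)

net <- build_network(network_spec("LCA", seed = 1))
net
#> MGC network (LCA, seed 1): 30 PNs, 30 LNs
#>    block n_possible n_nonzero   density mean_nonzero sign_ok
#> 1  pn_pn        420       190 0.4523810   0.08087039    TRUE
#> 2  ln_pn        900       190 0.2111111  -2.50669618    TRUE
#> 3  pn_ln        900       249 0.2766667   0.09352988    TRUE
#> 4  ln_ln        870       200 0.2298851 -15.01108033    TRUE
#> 5 orn_pn         60        24 0.4000000   1.22057852    TRUE
#> 6 orn_ln         60        48 0.8000000   1.29043964    TRUE
```

The `ln_ln` density of 0.23 reflects the sparse asymmetric LCA wiring
(target probability 0.25); densities below the connection probabilities in
the excitatory blocks come from sign rectification of weight draws near
zero.  Simulate a 500 ms pulse of a 0.25 : 0.75 blend and bin the PN
output:

```r
stim <- make_pulse_train(0.25, onset = 100, pulse_ms = 500)
tr <- simulate_network(net, stim, sim_config(duration = 700, seed = 42))
tr
#> MGC activity trace: LCA network, 30 PNs + 30 LNs, 700 ms at dt = 1 ms
#>   stimulus: ratio 0.250, 1 pulse(s); peak PN activity 1.000

resp <- bin_responses(tr)           # 30 PNs x 70 bins of 10 ms
v <- flatten_response(resp, code_length = 200)
length(v)                           # 30 PNs x 20 bins
#> [1] 600
ratio_class(0.25)                   # one of the 5 ratio classes
#> [1] 0.25
```

`plot(tr)` draws the PN/LN raster with the stimulus bar; higher-level
drivers (`trajectory_timing_ensemble()`, `ratio_decoding_experiment()`,
`specificity_curve()`, `interval_interference_experiment()`,
`correlation_map_experiment()`) run whole ensemble experiments from one
master seed and return means with standard errors.

A thin command-line front end is installed at `inst/exec/mgc`
(`mgc build | stim | simulate | inspect`) for driving single simulations
from a shell; networks and stimuli serialize to JSON, traces and maps to
CSV.

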