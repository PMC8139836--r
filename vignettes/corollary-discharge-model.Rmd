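---
title: "A corollary-discharge feedback model of thermotaxis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A corollary-discharge feedback model of thermotaxis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdtaxis)
```

## The model

*C. elegans* navigates temperature gradients as a biased random walk:
forward runs alternate with brief reversals, and runs pointing in favorable
directions are extended. `cdtaxis` implements a reduced dynamical-systems
account of how a *corollary discharge* (CD) — a copy of the motor command
fed back onto a first-layer sensory interneuron — can stabilize the
forward-run state against fluctuating thermosensory input.

The circuit has three layers. The thermosensory neuron (AFD) is a leaky
integrator of the input current and is eliminated by setting it to its
steady state $V_0 = V_{L0} + I_{input} R / g_{L0}$
(`afd_steady_state()`), which reduces the model to two variables — the
interneuron $V_1$ (AIY) and a motor-command variable $V_2$ standing for the
premotor circuit:

$$\tau_1 \dot V_1 = -g_{L1} V_1 + \alpha I_{input} + F_{12}(V_2) + C_1$$
$$\tau_2 \dot V_2 = -g_{L2} V_2 + F_{21}(V_1) + C_2$$

with the CD feedback $F_{12}(V_2) = w_{fb}\,\sigma(k_1 (V_2 - \beta_1))$
($\sigma$ logistic) and the motor drive
$F_{21}(V_1) = w_{21}\left[\gamma_1 \sigma(k_2 (V_1 - \beta_2)) -
\gamma_2 \sigma(-k_3 (V_1 - \beta_2'))\right]$, the difference between a
forward-promoting (AVB-like) and a reversal-promoting (AVA-like) premotor
pool. The locomotor state is read off the sign of $V_2$: forward when
$V_2 > 0$, reversal when $V_2 < 0$ (`motor_state_of()`; an exact zero keeps
the previous state — the model only defines the two open half-lines, and a
hysteresis-free tie-break keeps the rule deterministic). The feedback gain
$w_{fb}$ takes the values $+1$, $0$ and $-1$: positive feedback (CD intact),
no feedback, negative feedback.

### Two readings of the motor drive, and one calibration

Written with both pool sigmoids in the same orientation and the shipped
symmetric pool parameters ($\gamma_1=\gamma_2$, $k_2=k_3$,
$\beta_2=\beta_2'$), the two terms of $F_{21}$ cancel identically — the
drive would be the zero function and the motor command could never switch
sign. We therefore adopt the odd-symmetric reading above as the default
(`form = "odd"`), which with symmetric pools collapses to
$w_{21}\tanh(k_2 (V_1 - \beta_2)/2)$ — a genuine sign-switching max-like
competition between the two pools. The degenerate literal reading stays
available (`form = "literal"`) for comparison.

A second, related adjustment: with the published offset $C_1 = 0.5$ the
interneuron nullcline spans $V_1 \in [0.5, 1.5]$ under positive feedback,
but the published inflection point $\beta_2 = 1.5$ sits at the *edge* of
that range, so the nullclines can only touch asymptotically and the system
is monostable. The `"calibrated"` preset (default) keeps every other value
and moves $\beta_2 = \beta_2' = 1.0$ — the midpoint of the nullcline range
— which restores the intended geometry: with $w_{fb} = +1$ the nullclines
intersect three times and the flanking intersections are stable,

```{r}
find_fixed_points(circuit_params(wfb = 1))
```

while $w_{fb} \in \{0, -1\}$ leaves a single stable point. The `"literal"`
preset ships unchanged for reference. This is the smallest single-parameter
change we found that produces the stated bistability; nothing else in the
package depends on the choice beyond it.

Numerically, the phase-plane tools exploit that each nullcline is the graph
of an explicit function, so intersections are roots of a scalar gap
function in $V_1$: they are bracketed on a 201-point grid over $[-2, 3]$,
refined by bisection, polished by damped 2-D Newton iteration with the
analytic Jacobian (50 iterations maximum, residual tolerance $10^{-10}$,
duplicates merged within $10^{-6}$), and classified by the Jacobian
eigenvalues. Integration uses fixed-step classical RK4 with substep
$\min(\Delta t_{input}, \tau_1/20)$ — the system is smooth and non-stiff,
and a fixed step keeps trajectories bit-reproducible; step-halving agrees
to better than $10^{-5}$ sup-norm on the demonstration simulations.

### Persistence needs fluctuating input

The hallmark of the CD motif is *persistence*: with $w_{fb}=+1$ the
high-$V_2$ (forward) and low-$V_2$ (reversal) states survive input swings
that stay inside the bistable band, which for the calibrated model is
$|\alpha I| \lesssim 0.37$ (computable from `nullclines()` by scanning the
input). We quantify persistence with `autocorr_timescale()`: the first lag
at which the mean-subtracted, unbiased-normalized autocorrelation drops
below $1/e$, interpolated between lags, with `Inf` returned when no
crossing occurs within half the series (a constant series also returns
`Inf`, with a warning).

One consequence of determinism deserves emphasis, because it shaped the
default demonstration stimulus (`oscillating_input()`). Driven by a *pure*
periodic input, the settled response of this model is itself periodic for
every gain setting, and the autocorrelation of any non-constant periodic
signal must dip below $1/e$ within one period (its average over a period is
zero). A noise-free sinusoid therefore cannot produce a persistence
contrast at all. Real thermosensory drive is never noise-free, so the
demonstration input is a sinusoid of effective amplitude $0.25$ (inside
the bistable band) and period $40$ time units with per-sample Gaussian
sensory noise of sd $0.15$, sampled at $\Delta t = 1$ for $4000$ time
units. Under this input the positive-feedback model latches and flips
state only occasionally (timescales of roughly $2$–$7$ periods across
seeds), while the no-feedback and negative-feedback models track the
stimulus (timescales around $0.17$ periods). The amplitude and noise level
were fixed once, from the bistable-band geometry and a scan of this
qualitative behavior, before any downstream statistics were run.

## The navigating agent

`simulate_agent()` couples the circuit to a point agent on an unbounded
plane with a linear gradient $T(x) = c_T x$ (warm toward $+x$). Each step
(duration `step_dt`, default one time unit) proceeds **sense → integrate →
state → heading → move**: the input is the temperature change over the last
`sense_lag` steps, $I_{input}(t) = c_T (x(t) - x(t - \Delta t))$, plus
sensory noise; the circuit advances by RK4; the sign of $V_2$ sets the
state; the heading is kept within a bout, rotated by 180° into a reversal,
and redrawn uniformly on $[-180°, 180°)$ when a run starts; the agent then
moves `speed * step_dt` along its heading. Simulations start at the origin,
heading uniform, $(V_1, V_2) = (1, 1)$, in a forward run. Ordering the
heading update after the state update makes heading decisions depend on the
just-updated motor state; the arena has no walls because no boundary
behavior is defined. Klinotaxis (gradual steering) is deliberately absent —
the model isolates the biased-random-walk component.

### Input scaling and sensory noise

Two agent-level constants required choices the circuit model does not pin
down.

* **Drive per step.** The defaults ($c_T = 0.02$, $\alpha = 60$, unit speed
  and step) give an effective drive $\alpha c_T \cdot \text{speed} \cdot
  \text{step\_dt} = 1.2$ for motion straight along the gradient — about
  three times the half-width of the bistable band. This is deliberate: if
  the straight-run drive cannot leave the band, the positive-feedback latch
  can never be broken by cooling (runs would last forever and the gradient
  could not shape them), and the no-feedback model could never be pushed
  into a forward state at all. With drive 1.2, sustained steep cooling
  breaks the forward latch while shallow or brief cooling does not.
* **Sensory noise.** Gaussian noise of sd $0.15$ (after $\alpha$; the
  `noise_sd = 0.0025` default is expressed before $\alpha$) is added to
  each step's input. The noise-free printed rules make every bout
  absorbing on a linear gradient — within a straight bout the input is
  constant, so a settled state never changes and most agents freeze into a
  single infinite bout; no run/reversal alternation, and none of the
  cooling statistics, can arise. The noise sd sits well inside the bistable
  band, so the positive-feedback latch filters it while the no-feedback
  model's state flickers with it — which is precisely the mechanism under
  study.

Both constants were fixed once from this reasoning (the gain ordering of
population bias was robust across the whole scanned neighborhood,
drive $0.8$–$1.6$, noise $0.1$–$0.25$) and are user-configurable. With
them, populations of 200 agents per gain reproduce the expected ordering of
mean thermotactic bias ($+1 > 0 > -1$, adjacent rank-sum comparisons
significant after Benjamini–Hochberg adjustment), and cooling epochs during
forward runs are followed by run termination more often without feedback
than with it.

The hot loop is implemented in C++ (Rcpp) for population-scale runs; a pure
R reference engine (`engine = "r"`) consumes the RNG in exactly the same
order and is asserted equal to the compiled path in the test suite.

## Analysis pipelines

**Behavior.** `thermotactic_bias()` projects per-frame velocity on a
configurable warm axis and divides by speed; the plate assay's gradient
runs along $-x$ (bias $= -v_x/|v|$), the simulation's along $+x$, and one
sign convention serves both. Frames slower than 5% of the median speed are
excluded (the ratio is unstable near zero speed). `segment_runs()` uses
motor-state labels when available — labeled data (simulation and synthetic)
are the primary path — with a velocity-projection fallback (1 s boxcar,
3-frame-lagged heading proxy) for unlabeled tracks. Run durations are
binned by the angle of the start-to-end displacement in 30° bins centered
on the warm axis. Cooling epochs are maximal negative stretches of
boxcar-smoothed $dT/dt$ lasting at least 1 s; the post-cooling reversal
fraction uses a 2 s response window after the cooling offset (a caption
ambiguity between "2 s" and "2 min" is resolved as 2 s, and the window is
configurable) and duration bins with edges $\{1, 3, 7, 30\}$ s; empty bins
are reported missing, never as zero.

**Traces.** `ratiometric_activity()` computes $R = $ green/red and
$\Delta R/R_0 = (R - R_0)/R_0$ with $R_0$ the 1st percentile of $R$
(linear-interpolation quantile); per-neuron ROI extraction (the "top
pixels" averaging) happens upstream of this package. `otsu_binarize()`
maximizes between-class variance over a 256-bin histogram, ties broken
toward the lower threshold; the test suite asserts exact agreement with an
exhaustive maximizer. `fit_mixture()` fits univariate Gaussian mixtures for
$k = 1\ldots6$ by EM (k-means++ initial centers, uniform initial mixing
proportions, 5 restarts, log-likelihood tolerance $10^{-6}$, variance floor
$10^{-6}\times$ the sample variance) and selects $k$ by
$\mathrm{BIC} = -2\log L + (3k-1)\ln n$. The activation threshold is the
intersection of the *weight-scaled* densities of the two lowest-mean
components — the decision-boundary reading of "intersection point", solved
in closed form from the log-density quadratic, with a midpoint fallback
when no root lies between the means. Bouts of activation are maximal
supra-threshold intervals.

**Events and correlations.** Event-triggered matrices align activity to
event frames; unavailable edge frames stay missing and per-lag means use
what exists. Pre/post changes default to 5 s windows on each side of the
event (the window is not pinned down by the source analyses; the
optogenetic-style comparison uses its printed 2.5 s windows via the
`window` argument of `thermal_response_probability()`). State-conditioned
cross-correlograms are computed per constant-state epoch of at least 3 s
(mean-subtracting within the epoch) and averaged across epochs — epoch-wise
rather than globally masked, which avoids splicing artifacts at state
boundaries; restricted to a recording with a single state, they equal the
whole-recording correlogram exactly. Warming/cooling phases are sign runs
of the 0.5 s-smoothed stimulus derivative; the response-magnitude threshold
defaults to $0.25 \times \mathrm{IQR}$ of the activity, as the source
thresholds are shown but not printed.

**Statistics.** Rank-sum and signed-rank tests wrap `stats::wilcox.test`,
exact for small tie-free samples and otherwise using the tie-corrected
normal approximation *without* continuity correction, so that
uninformative comparisons (identical samples) report $p = 1$.
Benjamini–Hochberg adjustment wraps `stats::p.adjust`. Confidence intervals
are percentile bootstrap (B = 1000 by default; plain percentile rather than
BCa, since nothing more specific is warranted), deterministic given a seed.

## The synthetic-data generators

`synth_config()` fixes the study conditions for all recovery tests: frame
interval 0.83 s (about 1.2 volumes/s), 600 s recordings (longer where an
analysis needs more events), sinusoidal stimulus of amplitude 1 temperature
unit and period 30 s, exponential run/reversal dwells with means 20 s and
5 s truncated at one frame, an exponential calcium kernel with
$\tau = 1$ s, and 5% multiplicative channel noise, independent per channel
so the ratiometric correction is genuinely exercised. Archetype latents:
AFD follows the stimulus derivative; AIY carries a motor-state step plus a
stimulus response *gated by the forward state*; AVA and RME are reversal-
and forward-active. In `"ablated"` mode the CD is absent: AIY loses both
the gate and the motor term and tracks the stimulus in every state, and
AVA's bimodality is reduced. Behavioral tracks use the agent's heading
rules with an elevated run-termination hazard during cooling (mild in
wild-type mode, strong in ablated mode), which produces both the
direction–duration dependence and the post-cooling reversal contrast that
the analysis pipelines are asked to recover.

What the generators deliberately do not emulate: real dwell-time
distributions (exponential is an assumption; the bout model is pluggable),
indicator nonlinearity and bleaching, motion artifacts, multi-animal
interactions, and klinotaxis. Passing recovery tests therefore demonstrate
that the pipelines measure what they claim on data with known structure —
not that real recordings satisfy that structure.

## Problem sizes and reproducibility

Default problem sizes were chosen so the full suite exercises every
pipeline at meaningful statistical power: 200 agents per gain for
population comparisons, 2000 steps per agent, 4000 time units for the
persistence demonstration, 100 seeded replicates for the threshold- and
model-selection oracles, and 500 replicates for bootstrap coverage. Every
stochastic component takes an explicit seed, populations derive per-agent
seeds from a master seed, and the compiled and R simulation engines are
RNG-identical, so all results in the package are bit-reproducible.

## Known limitations

* The bistability calibration ($\beta_2 = 1.0$) is a modeling choice made
  to realize the stated dynamical regime; the source parameterization is
  retained but monostable.
* Persistence and navigation contrasts require fluctuating input; they are
  properties of the noisy regime, not of the noise-free equations.
* Activity units are arbitrary throughout; no physical calibration of
  $V_0$–$V_2$ or $I_{input}$ is implied.
* The velocity-based run segmentation fallback is a convenience for
  unlabeled tracks and is less reliable than labels near slow, curved
  stretches.
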