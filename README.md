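# cdtaxis

Corollary-discharge feedback in a reduced model of *C. elegans*
thermotaxis: circuit dynamics, agent-based navigation, and the analysis
pipelines that connect them to calcium-imaging and behavioral data.

## The scientific problem

During thermotaxis, *C. elegans* alternates forward runs with brief
reversals and biases this random walk by extending runs that point in
favorable directions. Calcium imaging shows that the first-layer
interneuron AIY encodes not only thermosensory input but also the motor
state — a *corollary discharge* (CD) relayed from the motor circuit (via
RIM) back into sensory processing. `cdtaxis` is for modelers and systems
neuroscientists who want to study, and test analysis code against, the
hypothesis that this feedback sustains forward-run activity states through
fluctuating sensory input.

The core model reduces the AFD → AIY → motor-command pathway to two
variables,

```
tau1 dV1/dt = -gL1*V1 + alpha*Iinput + F12(V2) + C1
tau2 dV2/dt = -gL2*V2 + F21(V1) + C2
```

with logistic feedback `F12(V2) = wfb * sigma(k1*(V2 - beta1))` and a
sign-switching motor drive
`F21(V1) = w21*[gamma1*sigma(k2*(V1-beta2)) - gamma2*sigma(-k3*(V1-beta2'))]`.
Forward runs correspond to `V2 > 0`, reversals to `V2 < 0`; the feedback
gain `wfb` is varied over +1 / 0 / −1 (positive, none, negative). With
positive feedback the calibrated model is bistable — its nullclines
intersect three times and the two flanking fixed points are stable — so
the motor state can latch and persist through input fluctuations. An
agent-based simulator couples the circuit to a point worm on a linear
thermal gradient (`T(x) = cT*x`), sensing temporal temperature changes and
following the standard heading rules (constant within a bout, 180° flip
into reversals, fresh uniform heading at run onset).

Around the model sit the analysis pipelines used on real recordings:
ratiometric activity `dR/R0` (baseline = 1st percentile of the green/red
ratio), Otsu binarization of premotor activity, Gaussian-mixture
segmentation of AIY activation (BIC over k = 1..6, k-means++
initialization, weighted-density intersection threshold), event-triggered
averages, state-conditioned stimulus cross-correlograms, thermotactic
bias, run segmentation, cooling-epoch statistics, Wilcoxon tests with
Benjamini–Hochberg adjustment, and percentile bootstrap CIs. Seeded
synthetic-data generators emit stimuli, two-channel traces and labeled
tracks with known ground truth so every pipeline has a parameter-recovery
test.

## A worked example

```r
library(cdtaxis)

## phase plane of the calibrated positive-feedback circuit
find_fixed_points(circuit_params(wfb = 1))
#>         V1         V2   eig1_re eig1_im   eig2_re eig2_im stability
#> 1 0.500003 -0.8482816 -1.491606       0 -1.508394       0    stable
#> 2 1.000000  0.0000000  3.092793       0 -6.092793       0    saddle
#> 3 1.499997  0.8482816 -1.491606       0 -1.508394       0    stable
#>       residual refined
#> 1 8.326673e-17    TRUE
#> 2 0.000000e+00    TRUE
#> 3 0.000000e+00    TRUE
```

Two stable states — one forward (`V2 = +0.85`), one reversal
(`V2 = -0.85`) — separated by a saddle: the circuit can latch its motor
state. Drive it with the oscillating-input demonstration and compare
persistence across feedback gains:

```r
set.seed(1)
input <- oscillating_input()        # sinusoid + sensory noise, period 40
v2_pos <- integrate_circuit(c(1, 1), input, circuit_params(wfb = 1))$V2
v2_no  <- integrate_circuit(c(1, 1), input, circuit_params(wfb = 0))$V2
autocorr_timescale(v2_pos, input$dt)
#> [1] 129.1308
autocorr_timescale(v2_no, input$dt)
#> [1] 6.286733
```

With positive feedback the motor command stays in one state for ~3 stimulus
periods; without feedback it tracks the stimulus (~0.16 periods). The same
contrast drives navigation (a couple of minutes for 600 agents):

```r
pop <- population_gain_comparison(gains = c(1, 0, -1), n = 200, seed = 1)
sapply(pop$bias, mean)
#>        pos       none        neg 
#>  0.5603415 -0.1482888 -0.4657063 
pop$comparisons
#>      a    b            p        p_adj
#> 1  pos none 3.655444e-26 7.310888e-26
#> 2 none  neg 2.159336e-05 2.159336e-05
```

Mean thermotactic bias (velocity projection toward warm, +1 = straight up
the gradient) orders the gains +1 > 0 > −1, with adjacent rank-sum
comparisons significant after BH adjustment.

## Pipelines from the command line

Configured pipelines (`simulate-circuit`, `simulate-agents`, `synth`,
`analyze-traces`, `analyze-behavior`) run through `load_config()` +
`dispatch()`, or the thin wrapper:

```sh
Rscript inst/scripts/cdtaxis.R --config my_run.json
```

Every run writes tidy CSV/JSON artifacts plus a `manifest.json` (config
echo, seed, package version) sufficient to re-run it exactly. See the
vignette `vignettes/corollary-discharge-model.Rmd` for the model's
assumptions, parameter choices, and known limitations.
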