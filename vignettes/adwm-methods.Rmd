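---
title: "Models and methods of the adwm working-memory platform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the adwm working-memory platform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(adwm)
```

`adwm` couples two models: a receptor-competition description of a single
synapse, which turns clinical doses into receptor activation levels, and a
conductance-based network of prefrontal cortex, which turns those activation
levels plus Alzheimer pathology into a working-memory span.  This vignette
explains both models, every tunable parameter that matters, the numerical
choices, and what the synthetic data used by the test suite do and do not
establish.

## The receptor competition model

Each receptor pool is a single population with total concentration
normalised to 1, for which the endogenous transmitter, drugs, metabolites
and radiotracers compete by mass action:

$$\frac{dR_i}{dt} = k_{on,i}\,C_i\,R_f - k_{on,i}\,K_{d,i}\,R_i, \qquad
R_f = 1 - \textstyle\sum_j R_j .$$

The dissociation rate is always the derived product $k_{on}K_d$.  At
constant concentrations the steady state is the competitive isotherm
$R_i = (C_i/K_{d,i})/(1+\sum_j C_j/K_{d,j})$, which
`equilibrium_occupancy()` evaluates in closed form; it is the analytic
oracle against which the integrator is tested to $10^{-6}$.

Free transmitter follows two processes: exponential decay with half-life
$\tau_{1/2}$ and quantal release on each presynaptic spike.  Release is
regulated by the autoreceptor (M2 for acetylcholine, 5-HT1B for serotonin)
through

$$r_{new} = r_0\Big[1 + r_{max}\Big(1 - \frac{2A^S}{A^S + B_0^S}\Big)\Big],$$

where $A$ is the autoreceptor activation read 150 ms before the release
(linearly buffered from the simulation history; before 150 ms of history
exists the tonic level $B_0$ is used), and by the spike-history
facilitation/depression factor
$1 + \sum_i [w_f e^{-k_f\Delta t_i} - w_d e^{-k_d\Delta t_i}]$.  The two
rules are written as multipliers of the base amount $r_0$, and the package
multiplies them, applying $r_0$ once.

**Simulation protocol.**  Phase 1 equilibrates every pool at a constant
500 nM free transmitter; the package replaces the numerical phase by the
closed-form isotherm, which is exact and removes an arbitrary
burn-in choice.  Phase 2 runs 5 s of tonic firing (7 Hz cholinergic — the
middle of the 6-8 Hz range; 1 Hz serotonergic); phase 3 runs a further
10 s over which mean activations are accumulated.  Integration is
classical fourth-order Runge-Kutta at 0.01 ms; because the decay law is
known in closed form, the Runge-Kutta stages see the exactly decayed
concentration at the half and full step, which keeps the step-halving
error of mean activations below $10^{-6}$ relative.

**Units.**  Concentrations are nM, times ms, rates per ms;
association rates are per nM per ms.  The cholinergic quantal increment
derives from 5.5 quanta of 70 molecules in a $10^{-16}$ L cleft
($\approx 6.4\,\mu M$ per action potential, the middle of the published
$5\text{-}20\times10^{-17}$ L volume range); acetylcholinesterase
saturation kinetics (pEC50 −6.6, Hill 0.9, turnover 25,000/s) are recorded
as constants, but clearance is implemented as the first-order 5 ms
half-life law, which is the quantity the dose chain manipulates.

**Calibrated affinities.**  The affinities of free ACh for the four
cholinergic pools are calibration constants of the platform.  The M1 value
(304 nM) is anchored so that the 8 mg galantamine chain
($l = 8/38$, half-life $5\,\text{ms}/(1-l) = 6.33$ ms) raises the mean M1
activation by the clinically derived 9.1%.  The M2 affinity (320 nM) puts
the tonic autoreceptor occupancy near the release rule's set point $B_0$.
The serotonergic association rate is $3\times10^{-4}$ per nM per ms:
autoreceptor occupancy must track the transmitter on the few-hundred-ms
scale of the release feedback loop (a diffusion-limited rate with the
5-HT1B equilibrium constant of 8.5 nM would unbind on a minute scale and
freeze the feedback).

## Dose chains and target engagement

Acetylcholinesterase inhibitors are characterised by one imaging anchor
each: the inhibition level $l$ at a reference dose.  The mass-equation law
$K_i = D(1-l)/l$ converts the anchors to clinical $K_i$ doses (15 mg
donepezil, 30 mg galantamine to the nearest mg, 18 mg rivastigmine);
linear pharmacokinetics gives $l = D/(D+K_i)$ at any dose, and inhibition
extends the ACh half-life to $\tau_0/(1-l)$.  The synapse model then
produces the treated cholinergic activations.

For the 5-HT6 antagonist SB-742457 the tracer (GSK215083) and drug
affinities are not public, so the platform ships the final activation
levels (40.6% placebo, 12.9%, 5.1%, 3.1% at 5/15/35 mg) as presets.  The
generic machinery — `simulate_displacement()` and
`invert_functional_concentration()` (bisection in log concentration, which
is monotone) — is exercised against the closed-form competitive isotherm in
the tests.

**Intra/extrasynaptic ratio.**  Voltammetry measures extrasynaptic
transmitter; intrasynaptic levels can be 1-20 times higher.  The platform
expresses the ratio as a release-scale multiplier and selects it by
scanning tracer-displacement error against imaging targets
(`scan_intra_extra_ratio()`); the shipped serotonergic preset uses the
selected ratio of 2.

## Presynaptic fitting and its identifiability

`fit_presynaptic_params()` fits the five presynaptic parameters
(sensitivity $S$, facilitation and depression weights and half-lives) to
forced-firing peak data by a coarse full-factorial search followed by
gradient descent in log-parameter space.  Two numerical choices matter:

* the descent is preconditioned by the diagonal curvature estimated from
  the same central-difference stencil — the five parameters act on very
  different scales, and an unpreconditioned gradient stalls on the
  resulting ridges; and
* the objective is only piecewise smooth (the peak switches between
  release events as parameters move), so steps are validated by a
  backtracking line search rather than trusted.

The peak observable has an intrinsic identifiability limit: when the
facilitation and depression half-lives are similar (e.g. 90 and 120 ms)
the two exponentials are nearly collinear and only the difference of the
weighted terms is determined — weight/half-life pairs trade off along a
ridge on which the data change by less than measurement resolution.  The
closed-loop recovery test therefore uses a generating physiology with
separated time scales (60 and 250 ms) and a stimulus battery of pulse
pairs at varying gaps (which trace the facilitation/depression curve
directly) plus sustained trains (which engage the autoreceptor and
identify $S$).  Slice-like protocols start from rest with a tonic warm-up
rather than from the 500 nM equilibration phase.

## The cortical network

The network has 80 four-compartment pyramidal cells (apical-distal --
proximal -- soma -- basal chain) and 40 two-compartment interneurons
(dendrite -- soma), with channel densities and geometry from the
compartment tables: fast sodium, persistent sodium, delayed-rectifier,
slowly inactivating and calcium-dependent potassium, and high-threshold
calcium channels on pyramids; fast sodium and delayed rectifier on
interneurons.  Gating follows first-order kinetics with the published
rate functions; removable singularities of the linoid forms are patched by
their limits, and the calcium-dependent channel is evaluated at the
shifted potential $V_s = V + 40\log_{10}(10^4[Ca]_i)$ with $[Ca]_i$ in
molar, floored at $10^{-8}$.

All pyramids form an all-to-all recurrent glutamatergic network (AMPA +
NMDA, including self-connections; a configuration switch removes
autapses) and contact every interneuron; a seeded 60% subset of
interneurons projects GABA-A synapses to all pyramids, and the remaining
40% contact only other interneurons.  Synaptic conductances are
unnormalised dual exponentials $\bar g(e^{-t/\tau_d}-e^{-t/\tau_r})$
(AMPA 0.5/2.4 ms, NMDA 2/130 ms, GABA-A 0.5/8 ms), NMDA currents are
multiplied by the magnesium block $1/(1+([Mg]/3.57)e^{-0.062V})$ at 1 mM,
and excitatory synapses land on the dendrites while GABA-A lands on the
soma.  A memory stimulus injects 1 nA into the somata of the 40
stimulated pyramids for 200 ms at $t = 2$ s and triggers an
mGluR5-type after-depolarization, an alpha-function current
$A\,(t/\tau)e^{1-t/\tau}$ with $\tau = 2.8$ s that keeps the attractor
excitable for several seconds.  Because the mGluR5 current is driven by
synaptically released glutamate, its amplitude scales with the surviving,
neuromodulated recurrent glutamatergic drive onto the stimulated
population — this is the pathway through which synapse and neuron loss
(and the drug couplings) reach the working-memory span.

**Numerics.**  Gates and membrane potentials advance by exponential Euler
at a fixed 0.025 ms step (gating functions and their per-step decay
factors are tabulated on a 0.05 mV grid).  Exponential Euler is the
NEURON-lineage implicit-style update and is unconditionally stable here;
the integrator is verified against the analytic membrane equation on a
leak-only compartment (0.1% tolerance) and by step-halving on isolated
cells, where spike counts must be preserved and spike times move by less
than 0.5 ms.  The full recurrent network is chaotic — step-halving changes
its trajectories through divergence, not integrator error — which is why
the convergence assertion uses the single-cell limit.

**Attractor termination.**  The recurrent excitation is AMPA-dominated:
a strongly NMDA-driven recurrent state is deeply hysteretic (once
ignited it survives lesions of a quarter of the population), whereas the
AMPA-dominated attractor collapses when the after-depolarization fades,
which makes the span graded in the surviving drive.  A calcium pool per
compartment (influx proportional to the high-threshold calcium current,
250 ms decay) feeds the calcium-dependent potassium channel and
terminates strong bursts; a second, slowly accumulating pool (8 s decay,
two orders of magnitude weaker influx) is negligible over a normal span
but caps the lifetime of the rare noise realisation in which the burst
would otherwise persist indefinitely.

**Inhibitory tone.**  Background activity is an independent Poisson
conductance train onto every cell.  Interneurons receive a stronger
stream than pyramids, so the inhibitory tone is set largely by the
network's surround rather than by local pyramidal drive alone.  This is
the decisive calibration choice for pathology: if inhibition were purely
feedback, deleting pyramidal cells would reduce excitation and inhibition
proportionally and the span would be insensitive to neuronal loss; with a
surround-driven inhibitory floor, excitatory loss is not compensated and
the span degrades with pathology, which is the behaviour the disease
model requires.

**Span readout.**  The raster is binned at 200 ms; a bin qualifies when
the number of distinct stimulated cells firing in it strictly exceeds
$M/2$ ($M$ = stimulated population size); the span is the time from the
first qualifying bin's start to the last qualifying bin's end.  The
stricter published alternative (at least 80% of the attractor) is
available as `threshold_frac = 0.8`.

## Pathology, genotype and interventions

Disease state is a linear accumulation on top of a trial baseline of 5%
synapse and 5% neuron loss: the calibrated slopes are 0.04%/week for
synapses and 0.25%/week for neurons.  Lesioning deletes the required
pyramidal cells split equally between the stimulated and unstimulated
halves (an odd count removes the extra cell from the unstimulated half,
preserving the attractor population), then removes the synapse-loss
fraction of surviving pyramidal-origin connections, excitatory-excitatory
and excitatory-inhibitory at the same rate; interneurons are never
deleted.  The cholinergic deficit (17.5% calibrated; 30% in the ApoE
experiments) scales the quantal ACh release, and the prodromal (MCI)
state is 3% synapse / 4% neuron loss with a 10% cholinergic compensation.
The placebo effect is a 7.5% increase of dopaminergic tone from week 12
onward (a configuration flag makes it transient).  ApoE4 adds 3% (one
allele) or 5% (two alleles) synapse loss, homozygotes additionally losing
10% of cholinergic tone.  Memantine multiplies the NMDA conductance by
$1-0.005$ on pyramid-targeting and $1-0.01$ on interneuron-targeting
synapses (NR2A/B vs NR2C/D placement).

## Coupling activations to biophysics

Every coupling uses the normalised relative change
$\varepsilon_X = (A_X - C_X)/C_X$ of treated against healthy-control
activation.  Excitatory synapses onto pyramids scale by
$(1+P_{D1syn}\varepsilon_{D1})(1+P_{\alpha7}\varepsilon_{\alpha7})$, AMPA
onto interneurons additionally by $(1+P_{D4}\varepsilon_{D4})$, GABA-A by
$(1+P_{D1gaba}\varepsilon_{D1})(1+P_{\alpha4\beta2}\varepsilon_{\alpha4\beta2})$
with the interneuron-interneuron class further modulated by 5-HT3.  The
muscarinic membrane rule $\Delta M = -4 + 6A_{M1} + 2(1-A_{M2})$ mV acts
on the delayed rectifier as $g' = g(1+\Delta M\,P_{M1})$; the package
applies the *change* of $\Delta M$ from the healthy control so that the
unperturbed network is exactly the calibration baseline.  The 5-HT6
cascade multiplies the dopaminergic, muscarinic and nicotinic activations
by $1 + P_{5HT6}\,(C-A)/C$: an antagonist lowers 5-HT6 activation and
must raise the downstream modulators, so the cascade uses the
antagonism-raises-modulators sign with the positive calibrated gain
(0.025); the literal sign is available as a switch.  The calibrated free
parameters are $P_{M1} = 0.075$ per mV, $P_{5HT6} = 0.025$, and the
relative $\alpha7$ vs $\alpha4\beta2$ weight of 2; the remaining synaptic
couplings are network calibration constants, all exposed in
`coupling_params()`.

## Calibration machinery

`doe_screen()` implements the two-level screen with $2n$ runs built from
fold-over pairs (run $k$: factor $k$ high, rest low; run $n+k$: the
mirror), estimating main effects as high-minus-low response means.  The
design is deliberately small and is not orthogonal: a weak factor bleeds
into a strong factor's estimate by a factor of order $1/n$, which is
acceptable for ranking drivers (the Pareto table).
`optimize_response_surface()` refines parameters by iterated star designs
with a separable quadratic fit and a trust region that grows on clamped
improving steps and shrinks on failures; its budget bounds the number of
response evaluations exactly.  `sensitivity_scan()` is the straight
one-at-a-time slice.

`correlate_clinical()` regresses the 28 ADAS-Cog effects on per-condition
mean spans.  Because the clinical effects are changes from each trial's
baseline, referencing the spans to any fixed baseline only moves the
intercept; slope, $r^2$ and $p$ (regression F-test) are invariant, so the
fit uses absolute mean spans.  Per-week sub-fits are reported for the 12,
26 and 52 week points.

## Problem sizes used by the tests

The test suite runs the synapse protocols at a 0.02-0.05 ms step with
2-5 s phases (the periodic steady state is reached within the first
second; the defaults keep the published 0.01 ms/5 s/10 s protocol).  The
healthy-network check uses ten 15 s trials; the clinical smoke
calibration runs the eight week-12 conditions at five 15 s trials each;
and the directional validations use twenty paired seeds per arm (13 s
at the prodromal stage, 10 s at the advanced stage, at a 0.05 ms step —
the paired contrasts compare arms under a common step, so the step
choice cancels).  The directional validations
(memantine, ApoE4) are paired comparisons over 20 seeds with common
random numbers: the placebo and treated arms of one seed share the
lesion and noise realisation.  A caveat the results inherit from the
network's chaos: trajectories under a sub-percent conductance change
decorrelate from their partner arm within about two seconds, so common
random numbers do not reduce the contrast variance much below that of
independent arms.  With per-arm span standard deviations of 1.2-1.4 s
and true contrasts of roughly half a second (memantine) or five
percentage points (ApoE4 relative span loss), the directional means
reproduce the published qualitative pattern — memantine slightly worsens
the prodromal network and helps the advanced one; an added fixed synapse
loss costs relatively more span early than late — but a significance
level of 0.05 would require on the order of seventy paired seeds.  The
validation tests report both facts: the direction of the means, and the
(not reached at twenty seeds) significance threshold.

## What the synthetic data show

The voltammetry-like fixtures emulate the *structure* of slice
calibration experiments — stimulus batteries and peak free-transmitter
readouts with Gaussian measurement noise — under the package's own
release model.  Passing the closed-loop recovery test shows that the
fitting machinery is correct and that the protocol identifies the
parameters when the data are informative; it does not show that any real
preparation satisfies the model, and the identifiability ridge described
above is a genuine property such experiments inherit.  Likewise the
clinical calibration exercises the full pipeline against the published
trial table; the couplings it selects are consistent with, not derived
from, molecular measurements.

## Known limitations

Single interneuron class, no explicit neuromodulator dynamics (effects
are averaged over the simulation), no pharmacokinetic time course (linear
PK, time-averaged engagement), point-conductance cleft (no spatial
diffusion), and a 120-neuron network in which losses are necessarily
granular (one pyramidal cell is 1.25% of the population).  The
butyrylcholinesterase pathway is deliberately excluded.
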