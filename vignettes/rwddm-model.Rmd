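---
title: "The RWDDM: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The RWDDM: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwddm)
```

## The model

The Rescorla-Wagner drift-diffusion model (RWDDM) couples an adaptive
interval timer to an error-correcting associative learning rule, so that a
single mechanism produces both the *timing* of conditioned responding
within a trial and the *dynamics* of associative strength across trials.

**Timing.** Every conditioned stimulus (CS) owns a noisy linear
accumulator $\Psi(t)$ that starts at stimulus onset and increments each
time step $\Delta t$ by

$$\Delta\Psi = A\,\Delta t + m\sqrt{A\,\Delta t}\,z,\qquad z\sim N(0,1),$$

a discretised Wiener process with drift $A$ (the slope, units 1/s) and
infinitesimal variance $m^2A$. An interval is timed by $\Psi$ reaching a
fixed threshold $\theta$; accumulation is not capped at $\theta$. The
first-passage time is inverse-Gaussian with mean $\theta/A$ and
coefficient of variation $m/\sqrt\theta$ — *independent of the interval
timed*, which is the model's account of timescale invariance
(`crossing_cv()`, checked against Monte-Carlo simulation in the test
suite). Rather than moving the threshold, the model adapts the slope once
per occurrence of the timed interval, at the target time $t^*$:

$$\Delta A = \alpha_t\,A\,\frac{\theta-\Psi(t^*)}{\Psi(t^*)}.$$

This is gradient descent on the squared slope error with the physical
$t^*$ replaced by the internal estimate $\Psi(t^*)/A$. Its fixed point is
$A = \theta/t^*$, and with $\theta = 1$ the stored quantity $1/A$ is an
exponential moving *harmonic* average of the experienced intervals
(verified against a closed-form oracle in the tests). Because timing
updates are driven by time markers (stimulus offsets as much as US
arrivals), the timer keeps adapting during extinction and preexposure —
the source of the model's accounts of faster reacquisition, re-timing in
extinction, and improved timing after preexposure.

**Representation.** The CS representation is a Gaussian receptive field
over the accumulator, $x(\Psi)=\exp(-(\Psi-\theta)^2/2\sigma^2)$: it peaks
at exactly 1 when $\Psi$ crosses $\theta$, i.e. at the remembered target
time. Two optional variants are provided behind configuration flags: a
linear-operator width adaptation $\sigma(n+1)=\sigma(n)+
\alpha_\sigma(0.35-\sigma(n))$ (used only by the latent-inhibition
design), and a leaky-integrator trace for early training. No rule is
imposed for *when* an organism would switch from trace to Gaussian
representation; the switch point is an open empirical question, so the
package exposes the primitives without a default schedule.

**Learning.** Associative strengths follow the Rescorla-Wagner update,
applied once per trial at US delivery (or at CS offset with $H=0$ on
non-reinforced trials), using the activations current at that moment:

$$\Delta V_i = \alpha_V\Big(\lambda_i-\sum_j V_j x_j\Big)x_i,
\qquad \lambda_i = \frac{H\,A_i}{\Psi_i(t^*)}.$$

The asymptote spreads the US magnitude $H$ over the internally estimated
delay (hyperbolic delay discounting), which yields the ISI effect: longer
intervals support proportionally less asymptotic responding,
$V_\infty = H A_\infty x/\Psi \approx H/t^*$ (`steady_state_v()`). The
summation term carries cue competition. Note that each element of a
compound has its *own* asymptote $\lambda_i$; when compound elements time
different durations the steady-state equations are inconsistent and the
$V$s drift apart without bound under prolonged compound training. This is
a structural property of the model, not a bug: it produces
duration-dependent blocking over short compound phases and an inhibitory
blocked CS when a short CS "blocks" a longer one, but it also means
blocked-versus-control comparisons depend on the length of the compound
phase (see Limitations).

Responding is $CR(t)=V\,x(\Psi)$, floored at zero for report ($V$ itself
may be negative — conditioned inhibition expresses through the summation
term, not through negative behaviour).

**Pearce-Hall extension.** With the `ph` flag the learning rate tracks the
absolute prediction error, $\alpha_V(n+1)=\alpha_V(n)+
\gamma(|\delta|-\alpha_V(n))$, $\delta=\lambda-Vx$. Nonreinforced
preexposure decays $\alpha_V$ geometrically from its novel-stimulus value
toward zero, producing latent inhibition once reinforcement begins. The
flag is enabled only in the latent-inhibition preset, keeping plain-RW
behaviour everywhere else. The preset interprets the adaptive rate's
novel-stimulus initial value as 0.4 alongside a non-adaptive default of
0.08 used when the flag is off.

## Parameters

| symbol | argument | meaning | default | units |
|---|---|---|---|---|
| $m$ | `m` | accumulator noise factor; crossing-time CV is $m/\sqrt\theta$ | preset-specific (0.15-0.25) | — |
| $\theta$ | `theta` | accumulation threshold | 1 | — |
| $\sigma$ | `sigma` | Gaussian representation width | preset-specific (0.18-0.425) | $\Psi$ units |
| $\alpha_t$ | `alpha_t` | slope adaptation rate | preset-specific (0.08-0.75) | — |
| $\alpha_V$ | `alpha_v` | associative learning rate | preset-specific (0.06-0.1) | — |
| $H$ | `H` | US motivational magnitude; 0 = US absent | preset-specific (4-40) | s$^{-1}$·$V$ |
| $\Delta t$ | `dt` | simulation time step | 0.01 s | s |
| $A(1)$ | `A1` | novel-stimulus initial slope | $10^{-3}$ | s$^{-1}$ |

Internal time is seconds with $\Delta t = 10$ ms. The arithmetic is
unit-consistent, so $10^{-3}$/s is the same slope as $10^{-6}$/ms; seconds
are used so that the asymptote arithmetic ($H=5$, $A_\infty = 1/5$ per
second giving $V_\infty\approx 1$ for a 5-s CS) reads in the units in
which results are reported. The deliberately low $A(1)$ makes the model
*over*-estimate novel durations for the first few trials; a high initial
slope would work formally but would amount to keeping a fast "standby"
pacemaker running.

## Protocol engine policies

* **Update timing.** Slope and association update at the trained time
  marker: US delivery on reinforced trials, CS offset on extinction
  trials. Peak (probe) trials apply *no* updates — probes are treated as
  too infrequent to re-time the stimulus, which is what preserves peak
  time and CV during peak-procedure extinction.
* **Compound response rules.** `sum` (default): the summing junction over
  all present representations. `faster_timer`: responding on a synchronous
  compound of separately trained CSs is guided by the element whose timer
  currently has the larger slope; ties break lexicographically by label
  for reproducibility. `averaged`: cross-modal compounds fuse into a
  single virtual representation with $A_{comp}=A_{low}/2+A_{high}/2$ (or
  $V$-weighted, `weighting = "v_weighted"`).
* **Mixed-interval stimuli.** A CS reinforced at two delays carries two
  independent representations; at each step behaviour is guided by the
  momentarily most active one, and at reinforcement both the slope and the
  association update go only to the representation maximally active there.
  The number of representations is declared in the design (2 for the
  mixed-FI and transfer-excitor stimuli, 1 elsewhere); no automatic
  representation-splitting criterion is applied.
* **On compound reinforced trials each timer updates from its own**
  $\Psi_i(t^*)$ (not the guiding timer's) — the conservative reading where
  every running timer registers its own interval.
* **Intertrial intervals are not simulated**: the designs do not time the
  context, so trials are concatenated events.
* **Conditioned-inhibition timing.** An inhibitor's timer times the
  arrival of US *omission* exactly as an excitor times the US: its slope
  updates at its offset on the nonreinforced compound trials.

## Numerical choices

* **Noise form.** The diffusion scaling $m\sqrt{A\Delta t}$ is the form
  under which the closed-form CV and timescale invariance hold, and it is
  the package default. A literal-linear alternative ($m\,A\,\Delta t\,z$)
  is available via `noise_form = "linear"` for sensitivity analysis; its
  within-trial variance vanishes with $\Delta t$, so it behaves
  near-deterministically at the default step and cannot reproduce the
  compound-peak left shift or the crossing-time CV.
* **Degenerate accumulation.** With a novel slope and noise, $\Psi(t^*)$
  can be nonpositive (it is approximately $N(A t^*, m^2At^*)$, and
  $At^*\ll\theta$ early on), where both $\Delta A$ and $\lambda$ divide by
  $\Psi$. A representation whose $\Psi(t^*)\le 10^{-3}\theta$ skips its
  updates for that trial; its activation there is below $10^{-2}$, so the
  forgone update is negligible and the timer re-registers on the next
  non-degenerate trial. The low-level `slope_update()`/`us_asymptote()`
  contracts signal errors instead, so the guard is an engine policy, not a
  silent change to the equations.
* **Peak detection.** Averaged stochastic curves are jagged, so
  `peak_time()` applies a centred 1-s moving average before the argmax
  (window exposed; ties take the earliest time). Superimposition is
  quantified as the RMSE between normalized curves interpolated onto a
  common 100-point grid over relative time 0-2; the 0.05 acceptance band
  used in the tests is an artifact-defined operationalization of curves
  that "roughly superimpose".
* **Pair-averaged early-window extinction measure.** `first_window_rate()`
  sums CR over the first 10 s of each trial, averages adjacent pairs and
  divides by 100; an odd trailing trial is dropped because the procedure
  presumes pairs.
* **CV convention.** `empirical_cv()` uses the population ($1/n$) standard
  deviation over the mean.

## The preset designs

`list_designs()` catalogues the ten built-in protocols with their phase
structures and parameter sets. Trial counts, durations, interval
distributions and probe mixing are fixed by the designs; a few quantities
the protocols leave open were set once as follows and not revisited:

* Peak-probe durations: 135 s in the VI/FI designs and 90 s in
  conditioned inhibition (stated by those protocols); 100 s (twice the
  training FI) in the compound-peak design and 60 s (three times the long
  CS) in temporal averaging.
* The compound-peak design interleaves 100 single-CS peak probes (50 A,
  50 B) alongside its 100 compound probes, because the analysis compares
  compound with single-CS peak times from the same runs.
* The latent-inhibition conditioning phase runs 250 reinforced trials so
  that preexposed and control curves demonstrably converge; its
  acquisition-phase US magnitude is $H=5$ in the
  acquisition/extinction/reacquisition preset, matching the worked
  steady-state arithmetic $V_\infty\approx1$.
* "Peak probes interleaved with probability 0.25" is realised as exactly
  1500 reinforced + 375 probe trials in a seeded random order, keeping
  trial counts exact.

All randomness flows from the single seed of `run_experiment()` (or, for
replicated runs, sub-seeds derived from the configuration's master seed),
so traces are bit-reproducible.

## What the simulations do and do not emulate

The protocol engine emulates idealised conditioning preparations: point
USs delivered at exact delays, perfectly discriminable CSs, no intertrial
or context conditioning, no response packets or motor noise, and a
response measure that is exactly $V x(\Psi)$. Passing tests therefore show
that the *model equations* produce the documented phenomena under the
stated schedules — they do not show that real animals' response rates
follow these curves, that acquisition speed depends on the
intertrial/trial ratio (not modelled), or that operant response topography
is captured. The redrawn empirical panels that motivated the protocols are
not part of the package and are never fitted.

## Problem sizes

The test suite runs each preset at its design size (e.g. 1875 VI trials,
1200 + 600 + 300 conditioned-inhibition trials, 15 replications of the
1000-trial compound-peak design) with $\Delta t = 10$ ms; property checks
use 3000-4000 Monte-Carlo realisations per crossing-time CV case and
100 seeded runs for the reacquisition comparison. A full run of the suite
and of the acceptance script each take a few minutes on one core.

## Known limitations

* **Accumulator-noise biases.** Because $E[1/\Psi] > 1/E[\Psi]$, the
  converged slope sits a few percent above $\theta/t^*$ (about
  $+m^2$ relative), and because the within-trial variance $m^2At$ grows
  with $t$, trial-averaged response curves peak 1-2 s before the mean
  crossing time at the default noise levels. Both effects are inherent to
  the diffusion noise that gives the model its timescale invariance. In
  the VI design they place the averaged peak slightly *below* the 27.1-s
  harmonic-mean reference, whereas a near-noiseless accumulator would
  track the moving harmonic average itself.
* **Inconsistent compound steady states.** As derived above, compounds of
  unequal durations have no joint $V$ fixed point; conclusions about
  blocking magnitude depend on the number of compound trials, and
  prolonged training drives the element strengths apart without bound.
* **Latent inhibition and early-training curve shape.** The Gaussian
  representation makes within-trial curves sigmoidal from the first trial,
  so improved timing after preexposure is carried by the timer but is
  barely visible in the response curves even with width adaptation; a
  two-state (trace-then-Gaussian) representation would be needed.
* **Temporal averaging** is predicted at the (possibly $V$-weighted)
  harmonic mean of the trained intervals; preparations whose compound
  peaks track a geometric mean are outside the model as implemented.
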