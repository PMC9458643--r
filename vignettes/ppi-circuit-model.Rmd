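---
title: "The startle-circuit rate model and its behavioural read-out"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The startle-circuit rate model and its behavioural read-out}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvappi)
```

## The model

`larvappi` simulates behaviour selection in the *Drosophila* larva
startle circuit with a seven-node firing-rate model. Each node is one
neuron category: mechanosensory chordotonal input (Ch), the Basin
projection neurons B1 and B2 whose relative activity determines the
behaviour, the feedforward inhibitory local interneurons iLNb and iLNa,
and the handle neurons Ha and Hb. The rate of node $i$ obeys

$$\tau_i \frac{dr_i}{dt} = -V_{0,i} - r_i + s_i
  + (r^{max} - r_i)\sum_j A^{ex}_{ij} r_j
  - \sum_j A^{in}_{ij} r_j, \qquad r_i \ge 0,$$

where $\tau_i$ is a time constant in arbitrary units (AU), $V_{0,i}$ an
activation threshold, $s_i$ the stimulus (non-zero only for Ch),
$r^{max}$ a saturation ceiling on excitatory transmission, and
$A^{ex}, A^{in}$ non-negative connectivity matrices fixed from synaptic
counts. The circuit logic: iLNa and iLNb inhibit each other and the
Basins asymmetrically (iLNa suppresses B2 strongly, iLNb suppresses B1),
so whichever interneuron class dominates disinhibits one Basin; the
handle neurons, driven by the Basins, feed back onto the interneurons.

Two entries of $A^{ex}$ — the chordotonal drives $w_{iLNa} \in
[0.5, 1.5]$ and $w_{iLNb} \in [1.5, 2.5]$ — are treated as an
individual-variability plane: every point of that plane is one model
individual, and area fractions over the plane play the role of
percentages of responding animals. The canonical example coordinates
(black dot $(0.95, 2.45)$, triangle $(1.25, 1.75)$, lead-interval point
$(1.10, 2.40)$, all as $(w_{iLNa}, w_{iLNb})$) fix this axis assignment;
the package validates weights against these ranges.

Two presets are built in. The `"adjusted"` set
($V_0 = (0, 0.1, 0.1, 0.1, 0.1, 1, 5)$, $r^{max} = 15$,
$\tau = (1, 30, \dots, 30)$, 50-AU stimulus, 10-AU cut-off) is the
regime in which the circuit expresses prepulse inhibition; the high
handle-neuron thresholds let prepulse-evoked activity outlast the lead
interval. The `"jovanic"` set ($V_0 = (0, 10, \dots, 10)$,
$r^{max} = 20$, $\tau = (1, 35, \dots, 35)$) is the original air-puff
study regime, retained as an alternative preset without any claim that
it reproduces PPI.

## Stimulus protocols

Stimuli are rectangular: a pulse (default amplitude $s_1 = 0.45$ for
sound-like drive, up to $2.0$ for strong air-puff-like drive; 50 AU
long) optionally preceded by a 4-AU prepulse of the same amplitude —
prepulse and pulse differ only in duration, as in the behavioural
experiments. The lead interval (default 30 AU) is measured from prepulse
offset to pulse onset; an onset-to-onset convention is available
(`lead_mode`). The prepulse starts at $t = 20$ AU, and the pulse onset
is computed identically whether or not the prepulse is enabled, so
paired runs are time-aligned. Simulations extend 150 AU past pulse
offset so activities relax toward baseline; all of these are arguments
of `stimulus_protocol()`.

## Numerical scheme

Dynamics are integrated with the classic fourth-order Runge-Kutta
method, default step `dt = 0.05` AU. Two conventions matter:

* **Stimulus sampling.** The rectangular waveform is sampled once per
  step at the left node, so each step lies entirely within one
  constant-stimulus segment provided switch times are multiples of
  `dt` (true for all defaults). RK4 then retains full accuracy across
  onsets; the Ch node, which is linear and uncoupled, matches its
  piecewise-exponential closed form to well below 1e-6 at the default
  step — the package's primary integration oracle, asserted by the test
  suite.
* **Rectification.** Rates are non-negative. The state is clamped to
  $\max(0, r)$ after every full step, *and* the RK4 sub-stage states are
  clamped before each drive evaluation, so the vector field is only ever
  evaluated at feasible states. Evaluating drives at infeasible
  (negative-rate) sub-stage states looks harmless but degrades the times
  at which rates leave the zero constraint to first-order accuracy in
  `dt`; bout durations near the classification cut-off then creep
  appreciably with each step halving. With sub-stage clamping they are
  stable across step halvings, and halving the step changes no label on
  the test landscape (asserted by the test suite).

Silenced neurons have rate and derivative held at exactly zero,
equivalent to removing the node. The initial state is the rectified
resting point $r = 0$. Non-finite states abort with the offending time
point. Landscape sweeps integrate all grid points as one vectorized
batch; coupling sums are accumulated term by term in a fixed order so a
batched column is bit-identical to a single-point run (the test suite
asserts sub-grid/per-point equality).

## Behaviour classification

Basin activities are normalized, $\hat r_i = r_i / r^*_i$, by a
**normalization reference**: the response of the reference individual
($w_{iLNa} = 1$, $w_{iLNb} = 2$) to a sustained $s_1 = 0.5$ input.
`r*` is the plateau (the run is 500 AU, by which the approach to steady
state is converged far below the classifier's sensitivity). The
reference condition is conventionally stated only as the maximum of the
response at $s_1 = 0.5$, without a stimulus duration; the package uses
the sustained-input maximum because a 50-AU reference pulse leaves the
Basins well short of their plateau, and with those inflated normalized
activities the model loses its no-reaction region entirely and fails to
reproduce the canonical example trials. The saturated reference
reproduces the full qualitative battery. References are cached keyed on
the complete parameter set, so changing `r_max` (the mutant surrogate)
recomputes `r*` under the altered parameters by default; pass a frozen
reference explicitly to keep wild-type normalization.

Each time point is labelled by the selection conditions with thresholds
0.8 (ratio) and 0.5 (activity):

* **n.r.** if $\hat r_{B1} \le 0.5$ and $\hat r_{B2} \le 0.5$;
* otherwise **hunch** if $\hat r_{B2}/\hat r_{B1} < 0.8$, else **bend**.

In their strict form the hunch and bend conditions also require *both*
normalized activities to exceed 0.5, which leaves mixed states (one
Basin above, one below) unassigned; we evaluate the n.r. condition first and assign
all remaining points by the ratio, which makes the partition exhaustive
and reproduces the example trials (a Basin-1-dominant response with a
suppressed Basin-2 must still count as a hunch). The literal reading is
available as `classifier_thresholds(rule = "literal")`. A zero
$\hat r_{B1}$ in the ratio branch is treated as infinite ratio (bend).

The trial outcome considers $t \ge$ pulse onset: maximal same-label runs
become bouts (duration = run length × `dt`), bouts shorter than the
10-AU cut-off are discarded, and the outcome is n.r. (nothing survives),
the common label, or a hunch-bend / bend-hunch sequence ordered by first
occurrence. Two same-label bouts split by a gap still yield that label —
a sequence requires a change to the *other* behaviour. Raising the
cut-off can only push outcomes toward n.r. (property-tested against a
brute-force scanner).

## The experiment battery

* `sweep_landscape()` classifies every grid point independently under
  one condition and `behaviour_fractions()` turns label counts into
  area fractions, with the grouping schemes used for figure-level
  comparisons (first-behaviour counting; sequence-inclusive hunch/bend
  groups; startle vs n.r.). "Startle" means any non-n.r. outcome,
  sequences included — both hunch and bend are startle behaviours, and
  the grouped output keeps either aggregation available.
* `change_map()` pairs per-point outcomes without/with prepulse.
* `persistence_map()` records each neuron's rate at pulse onset of the
  with-prepulse run (raw rates by default, `normalized = TRUE` divides
  by `r*`; the figure colour scale is unspecified, so both are exposed).
* `lead_interval_sweep()`, `silencing_experiment()` (strong stimulus
  $s_1 = 2$, no prepulse, unsilenced control on the same grid) and
  `rmax_experiment()` (prepulse suppression at each ceiling) wrap the
  standard comparisons.

Default grids are 101 × 101 (0.01 increments, endpoints inclusive). The
test suite and the acceptance script run 11 × 11 (0.1 increments) and
5 × 5 sub-grids, which resolve every grid-level comparison they assert
while keeping a full run in seconds; the full grid is a
`grid_spec(increment = 0.01)` away and needs no other change.

## What the model does and does not show

Within the package, the adjusted parameters reproduce, qualitatively:
prepulse inhibition at the black dot and its absence at the triangle
dot; broadening of the n.r. region with a prepulse together with fewer
hunches and more bends; the inverted-U dependence of suppression on the
lead interval (maximal at 30 AU among 10/30/50); the opposite
hunch/bend shifts under iLNa versus Hb silencing; weaker prepulse
suppression and a smaller iLNb (but larger Ha/B1) prepulse residual at
$r^{max} = 20$; and iLNb-residual dominance at exactly those grid
points whose hunch the prepulse removes. These are the checks in
`tests/testthat/test-acceptance.R`; none of them are statements about
real larvae beyond the circuit hypothesis they encode.

Limitations worth keeping in mind:

* The w-plane is sampled uniformly; real populations of larvae need not
  be uniform over it, so area fractions are not percentages of animals.
* Rates are deterministic; there is no trial-to-trial noise, no
  spiking, and no plasticity. The `seed` config field is reserved.
* Near the bout cut-off the outcome is inherently knife-edged: the
  prepulse works precisely by pushing hunch durations across 10 AU, so
  with-prepulse labels at a handful of boundary grid points can depend
  on the integration step in any finite-precision scheme.
* Higher brain areas, sensory transduction and motor execution are out
  of scope; the stimulus is an abstract drive to Ch.
* The axis assignment of the weight ranges follows the canonical
  example coordinates (see above). It matters: under the swapped
  assignment the prepulse residual lands in iLNa rather than iLNb and
  no suppression of the startle response occurs at all.

## Session info

```{r}
sessionInfo()
```
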