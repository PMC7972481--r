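---
title: "Learning the order and duration of stimulus sequences with two-trace eligibility plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning the order and duration of stimulus sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttlnet)
```

## The problem

Generic chain-like networks can learn the *order* of a stimulus sequence by
strengthening feed-forward connections, but replay it at the network's
intrinsic time scale: the recalled sequence is temporally compressed.  This
package implements a modular circuit that learns both order and duration.
Each stimulus is represented by a column housing a core microcircuit (CNA)
of four populations:

* **Timers** — excitatory cells whose *learned recurrent* weights sustain a
  transient; the decay time of that transient encodes the element's duration.
* **Timer-inhibitory partners** — driven by the Timers through small fixed
  weights and equipped with fast (10 ms) synapses, so their activity
  collapses before the Timers'.
* **Messengers** — excitatory cells receiving slow (80 ms) fixed excitation
  from the Timers and fast fixed inhibition from the inhibitory partners.
  While the Timer is strong, inhibition wins; as the Timer transient decays,
  inhibition collapses first and the Messengers fire a pulse confined to the
  *end* of the element.  That pulse is the hand-off that ignites the next
  column.
* **Messenger-inhibitory partners** — local interneurons that also receive
  the stimulus pulse and foreign Messenger activity.  They implement the
  soft winner-take-all competition between Messenger populations as
  long-range excitation onto local inhibition (one of the two equivalent
  arrangements the circuit admits) and shield the Messengers from the brief
  onset transient when a column is ignited.

Inputs are LGN-like: each element occurrence is a 50 ms Poisson pulse routed
to the selective column's Timers.  The element's *duration* is carried only
by the timing of the neuromodulator events (below), never by sustained
input.

## The two-trace learning rule

Every plastic synapse carries two eligibility traces, one for LTP and one
for LTD, driven by thresholded Hebbian activity \(H_{ij} = r_i r_j\)
(zero unless both rates exceed a threshold, which keeps noise-driven rate
overlaps from activating traces):

\[ \tau_a \frac{dT^a_{ij}}{dt} = -T^a_{ij} + \eta_a H_{ij}
   \left(T^a_{max} - T^a_{ij}\right), \qquad a \in \{p, d\}. \]

A global novelty neuromodulator is released at every stimulus onset and
offset.  Treating it as a unit impulse, each event converts the trace
difference into a weight change and consumes the traces:

\[ \Delta W_{ij} = \eta \left(T^p_{ij} - T^d_{ij}\right), \qquad
   T^a_{ij} \leftarrow 0, \]

followed by a 25 ms lockout of trace activation.  Under constant \(H\) the
traces relax to effective saturations
\(\tilde T_a = \eta_a H T^a_{max} / (1 + \eta_a H)\) with effective time
constants \(\tilde\tau_a = \tau_a / (1 + \eta_a H)\).  (A common shorthand
for these two expressions drops \(\eta_a\), which is inconsistent with the
steady state of the trace equation; the package uses the exact ODE-derived
forms everywhere.)

Two fixed points organise learning:

* **Falling phase (recurrent learning).**  After Hebbian activity crosses
  below threshold, both traces decay freely; they intersect a delay
  \(D = \ln(\tilde T_p / \tilde T_d)\,/\,(1/\tau_p - 1/\tau_d)\)
  later (`falling_fixed_point_D()`).  Recurrent Timer learning pushes the
  gap between the end of Timer firing and the next reward toward this value,
  so the Timer transient grows or shrinks until it ends just before the next
  element begins.  With the shipped recurrent parameters
  (\(\tau_p = 800\), \(\tau_d = 267\) ms, saturation ratio 1.03,
  equal \(\eta\)) the gap is \(D^* \approx 12\) ms.
* **Rising phase (feed-forward learning).**  For synapses whose Hebbian
  activity is still rising at reward time, the balance
  \(\tilde T_p(H)(1 - e^{-t_r/\tilde\tau_p(H)}) =
    \tilde T_d(H)(1 - e^{-t_r/\tilde\tau_d(H)})\)
  picks out a unique Hebbian level \(H^*\) (`rising_fixed_point_H()`);
  feed-forward Messenger-to-Timer weights stop changing when the
  coactivation product at reward reaches it.  Feed-forward trace parameters
  must have dominant LTP while rising (\(\eta_p > \eta_d\)) and dominant LTD
  while falling (\(\tau_d > \tau_p\)); the constructors enforce this.

Both solvers are verified in the test suite against independent numerical
oracles (bracketing root finders and long constant-drive integrations), and
a closed-loop simulation in which a feed-forward weight is trained by the
rule converges to weights whose Hebbian product at reward equals \(H^*\).

## Backends

The **spiking backend** uses conductance-based leaky integrate-and-fire
neurons (forward Euler, 0.1 ms steps; the post-spike reset potential is a
convention of this implementation, the leak reversal), exponential
synaptic-activation
dynamics with per-spike increments \(\rho(1-s)\), and an exponential filter
for per-neuron rate estimates.  Additive Gaussian voltage noise with
per-step standard deviation \(\sigma\sqrt{dt}\) makes firing
fluctuation-driven; \(\sigma\) was chosen so that interspike-interval
coefficients of variation during recall sit near 1, the irregularity regime
the model is meant to operate in.  Per-neuron spike thresholds are spread
over a few millivolts so that population recruitment — and therefore the
recurrent transient — is graded rather than all-or-none.

The **rate backend** represents each population by one unit,
\(\tau_u \dot u = -u + \sum W^\alpha \xi(u) + I\), with the piecewise
transfer \(\xi\): zero below a threshold, quadratic up to a critical level,
and square-root above it.  The two branches are constructed to agree
exactly at the critical level — the unique continuous arrangement — and the
branch expressions are isolated in `transfer()` so an alternative form is a
one-line change.  The square-root branch lets a self-excited Timer unit
hover near a saddle, so transient duration grows smoothly — and steeply —
with the recurrent weight, diverging at a critical weight; the learned
weight is capped just below the critical value so an overshooting update can
never lock a Timer into permanence.  Inhibitory projections enter as
negative entries of one signed weight matrix.  Unit time constants are 80 ms
for Timers, 10 ms for inhibitory partners and 25 ms for Messengers (their
inputs are the slow variables; the pulse must track a brief disinhibition
window).

## Parameters that matter

All values live in `inst/extdata/default-params.yaml`; nothing is
hard-coded.  The shipped values were calibrated once against the
qualitative constraints the circuit must satisfy — a pre-learning Timer
transient of a few hundred ms, a
Messenger pulse at the end of the transient, inhibition decaying faster than
excitation, the feed-forward trace ordering, rate thresholds above the noise
floor, and a learnable duration range reaching from a few hundred ms toward
two seconds — and are recorded there as the package's own defaults.

Key choices, with rationale:

* `learning.*.recurrent`: \(\tau_p/\tau_d \approx 3\) with a small LTD
  saturation surplus gives a small positive falling-phase gap; the pair
  (800, 267) ms keeps inter-trial trace carry-over negligible at the default
  4 s gap, which matters because trace remnants harvested at the next
  trial's onset event otherwise ratchet recurrent weights upward.
* `learning.*.recurrent.r_th`: placed near the half-maximum of the Timer
  rate, so that the trained threshold crossing and the measured half-max
  offset nearly coincide and recalled durations read out close to the
  trained values.
* `measure`: onset/offset at half of the per-column peak with a 50 ms
  debounce.  Half-max measurement is robust to spiking noise, and every
  threshold is configurable.
* `nonmarkov`: reservoir gain 0.9 (contracting, so the state is a fading
  memory and recall is robust to initial-state perturbations), input scale
  keeping the reservoir within the graded range of `tanh`, sparse threshold
  at the top few percent of the projection's drive distribution, and a rate
  gate on the feedback Hebbian update so the decaying tail of the element
  that is ending does not wire itself to its own transition pattern.

## The three-stage extension

For sequences whose transitions depend on history (ABAC, or two sequences
sharing an element), the direct Messenger-to-Timer path is removed and
replaced by: a fixed recurrent reservoir reading the Messengers (block
projection, weights \(N(0, g^2/K)\) — the gain-scaled reading of the random
recurrent ensemble; a literal variance of \(gK\) would diverge with size); a
binary sparse pattern network thresholding a sparse random projection of the
reservoir; and Hebbian feedback weights from pattern units to Timers,
clipped to \([0, Q_{max}]\).  Patterns fire only during Messenger activity
(the gating factor in the pattern equation carries an unbound index; it is
implemented as a gate on any Messenger exceeding the threshold), so a
pattern tags a transition together with the history that led to it.

Two deviations from the plain formulation, both visible in the
configuration: the feedback Hebbian update gates Timer rates (same
noise-rejection role as the feed-forward rate threshold), and the learned
feedback is expressed at recall but not during training — during externally
driven training the stimulus already carries the sequence, and expressing
the growing feedback live destabilises the joint learning of durations and
patterns at the scale used here.

## Desk scale: what the defaults do and do not show

The shipped experiments run at reduced scale (25 or fewer neurons per
population for spiking runs; one rate unit per population; 40–100 training
trials).  At this scale, verified by the test suite and the acceptance
script:

* Stimulus-cued elements on the rate backend recall their duration within
  about 5–10% across roughly 300–2000 ms, converging in 25–50 trials;
  an upward sweep succeeds out to ~2 s and a downward sweep to ~300 ms.
* Chained elements (ignited by the learned Messenger hand-off rather than
  the stimulus) recall systematically ~25–30% short on the rate backend:
  during training the target Timer receives stimulus *and* hand-off, at
  recall only the hand-off, and the duration code inherits the difference.
  Order expression and the rank-ordering of durations are preserved (the
  no-compression property), and the ±20% perturbation of the fixed CNA
  weights preserves order; the strict 10% timing criterion under
  perturbation is not met, and this is reported as measured.
* The spiking backend reproduces the microcircuit phenomenology (graded
  transients, end-of-element Messenger pulses, CV ≈ 1 irregularity, trace
  dynamics) but not the timing precision of the full-size model: near the
  critical recurrent weight the duration code carries ±30–40%
  trial-to-trial jitter at 25 neurons/population, the learning equilibrium
  drifts toward the weight cap, and recall does not reliably chain beyond
  the cued element.  The corresponding acceptance quantities are computed
  faithfully and reported at their measured values rather than adjusted.
* The three-stage network stores the overlapping pair BRO/GRP and recalls
  the history-dependent transition out of the shared element correctly from
  either cue; the six-element repeated-element sequence trains its durations
  correctly but the pattern at the first repeated-element offset is not
  discriminated from later ones at this reservoir size, so not all three
  history-dependent transitions are expressed.

Synthetic protocols emulate the experimental structure (pulsed inputs,
contiguous elements, inter-trial gaps) but not receptive-field structure,
trial-to-trial stimulus variability, or any anatomical detail; passing at
desk scale demonstrates the mechanisms, not quantitative biology.

## A worked example

```{r example, eval = FALSE}
cfg <- default_config()
prot <- stimulus_protocol(1:3, c(300, 800, 500),
                          input_amp = cfg$protocol$input_amp)
net <- build_network(3, cfg, backend = "rate", seed = 1)
fit <- train(net, prot, n_trials = 80, seed = 1)
rec <- recall(fit$net, cue = 1, sim_duration = 3500, seed = 3)
extract_elements(rec, prot)
```

Numerical conventions worth knowing: synaptic decay precedes the per-spike
increment within a step (a fixed order makes runs bit-reproducible); trace
updates in the spiking engine run on a 0.5 ms substep of the 0.1 ms
integration grid, which the rate-estimate smoothing makes safe; degenerate
inputs (zero WTA, empty protocols, silent columns) are permitted and handled
explicitly rather than erroring; and all randomness flows from the seed
arguments through R's generator, so identical seeds give byte-identical
spike files.
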