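---
title: "Model and methods: spiking cerebello-cortical simulation of delay eyeblink conditioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Children with autism spectrum disorder (ASD) acquire conditioned eyeblink
responses *faster* than typically developing children, and the conditioned
response (CR) peaks *earlier*. `debcsim` implements a systems-level spiking
model of the cerebello-cortical circuit that links these two behavioural
signatures to two anatomical features of the autistic brain: a reduced
Purkinje-cell count and hyper-connectivity (modelled as faster signal
transmission) between the cerebellum and sensory-motor cortex.

Two parallel circuits share one architecture: a *motor* pathway
(granule cells GRm → Purkinje cells PCm → dentate nucleus DNm → primary
motor cortex M1) and a *cognitive* pathway routed through medial prefrontal
cortex (GRc → PCc → DNc → mPFC → M1). The conditioned stimulus (CS, a
100 spikes/s regular train over 300 ms) reaches the granule layers and the
dentate nuclei; the unconditioned stimulus (US, 100 spikes/s over the final
20 ms of the CS) reaches the inferior olive (IO), whose climbing fibres
teach the Purkinje cells. The population firing rate of M1 is the CR
read-out.

## Neurons and numerics

Every population consists of leaky integrate-and-fire neurons with
exponential-shaped postsynaptic currents:

$$\tau_m \dot V = -(V - E_L) + \frac{\tau_m}{C_m}\,(I_e + i_{ex}(t) + i_{in}(t)),
\qquad \tau_{syn}\,\dot i_{ex/in} = -i_{ex/in},$$

with $C_m = 250$ pF, $\tau_m = 10$ ms, $E_L = V_{reset} = -70$ mV,
$V_{th} = -55$ mV, $t_{ref} = 2$ ms, $\tau_{syn} = 2$ ms (the documented
defaults of the reference neuron model this type reproduces). A connection
weight is the postsynaptic-current increment in pA per presynaptic spike;
its sign selects the excitatory or inhibitory channel. The subthreshold
system is linear, so each step applies its exact exponential propagator —
there is no integration error below threshold, which is what lets the test
suite compare the stepped dynamics against the closed form
$V(t) = E_L + I_e\tau_m/C_m + (V_0 - E_L - I_e\tau_m/C_m)e^{-t/\tau_m}$ at
relative error $<10^{-6}$. Threshold crossings are detected at end of step;
spiking neurons reset and clamp for the refractory period. Under these
parameters the rheobase is $C_m(V_{th}-E_L)/\tau_m = 375$ pA: the 370 pA
bias of granule, olive and dentate cells pre-activates them just below
threshold ("silent until stimulated"), while the 380 pA Purkinje bias
produces weak tonic firing (~22 spikes/s) that supplies the pre-learning
inhibition of the dentate nuclei.

The default resolution is $dt = 0.1$ ms, the reference simulator's default
(configurable; all delays and spike times snap to this grid). A session is
2,500 ms; delayed deliveries travel through per-projection ring buffers, and
any event scheduled past the session end is dropped *and counted* in a
`dropped_events` diagnostic rather than silently lost (the default layout
drops none).

## Architecture and the ASD manipulations

Cell counts (control): 768 GR, 24 IO, 24 PC and 12 DN per pathway, i.e.
1,536/48/48/24 in total. The cortical population sizes are a package
choice: both M1 and mPFC use 24 neurons, the scale of the other small
populations. Weights (pA): CS→GR 500, CS→DN 500, US→IO 100,
IO→PC −500 (one-to-one; all other projections all-to-all), IO→DN 60,
PC→DN −7, DNm→M1 100, DNc→mPFC 50. Plastic initial values: GRm→PCm 5,
GRc→PCc 20, mPFC→M1 0.1. Per subject, uniform draws set the
noise-to-dentate weight ([0.1, 0.5] pA), the cortical biases
($I_e^{M1}, I_e^{mPFC} \in [300, 365]$ pA) and the prefrontal-motor
learning rates ($\beta \in [0.2, 0.5]$, $\gamma \in [-0.035, -0.015]$).
One integer seed drives a subject end-to-end: the parameter draws first,
then every session's noise, off a single RNG stream.

The ASD condition changes exactly two things: each Purkinje population
shrinks from 24 to 15 cells (30 total, within the reported 24–50% loss
range), and the six cerebello-cortical sensory/motor projections
(CS→GRm, CS→GRc, CS→DNm, CS→DNc, US→IO, DNm→M1) transmit with a 50 ms
delay instead of 100 ms. Every other projection uses the conventional
minimal 1 ms synaptic delay. With 15 Purkinje cells facing 24 olive
cells, the one-to-one climbing-fibre map pairs the lowest-index cells and
the nine surplus olive cells keep only their dentate projection — a
deterministic convention independent of the seed.

## Plasticity

**Parallel fibre → Purkinje (LTD/LTP).** Each IO spike arriving at an
active Purkinje cell depresses every afferent synapse by the discrete
convolution of a temporal eligibility kernel with that granule cell's
spikes in the current trial, clamped at zero. The kernel is

$$K(t) = a\,\exp(-|(t+c)\,a|^{b}/f)\;(-\sin((t+c)\,e))^{d},$$

$a = 15$, $b = 1.8$, $d = 0.75$, $f = 1.3$, $e$ Napier's constant, defined
on $-\pi/e < t + c < 0$ and zero elsewhere; $c$ translates it along the lag
axis (0.1 s motor, 0.2 s cognitive). The constants admit more than one
algebraic placement; the package adopts the most literal one and calibrates
it against the reference peak positions of 150 ms (motor) and 250 ms
(cognitive) before the olive spike: the numerical argmax lies at 147.3 and
247.3 ms, matching those values at their stated precision (they are quoted
to the nearest 10 ms), and because the two kernels are exact translations
their 100 ms separation is grid-exact. A scan of the alternative placements
(moving $f$ inside the envelope, combining exponents, scaling the sine)
brackets the peak between 135 and 162 ms without landing exactly on
150.0 ms, so the literal reading is retained.

"Active" means the Purkinje cell spiked within the preceding 50 ms (a
bounded, testable criterion; the window is a visible field of the plastic
state). LTP is non-associative: each parallel-fibre spike arriving at an
active Purkinje cell adds $\alpha = 0.05$, except in a step where an olive
spike reaches the same cell (the branches are exclusive). Applying
$\alpha$ once per presynaptic spike, rather than per time step, bounds
potentiation by presynaptic activity; a per-step reading diverges. Spike
buffers clear at every trial boundary so LTD integrates only the current
trial's CS train.

**mPFC → M1 (coincidence rule).** When a motor neuron spikes, every
afferent prefrontal cell that spiked within the preceding 40 ms is credited
with contributing and potentiates by $\beta$; all other afferents depress
by $\gamma < 0$ (the depression branch is the exact complement of the
coincidence condition).
Weights clamp to $[0, w_{cap}]$ with $w_{cap} = 50$ pA. The cap is chosen
at pathway-aggregate parity with the direct dentate drive: 24 mPFC cells at
50 pA equal 12 DN cells at 100 pA, so the fully potentiated *modulatory*
pathway can at most match, never dominate, the primary one. (A per-synapse
cap of 100 pA lets the prefrontal volley reach twice the dentate volley;
M1 then fires doublets, the CR-rate denominator doubles, and the control
group's acquisition curve inverts — contradicting the behaviour the model
is meant to produce.)

## Protocol and read-outs

Each of the 10 training sessions is one 2,500 ms run: a CS-only test probe
(CS over [0, 300] ms, measurement epoch to 550 ms) followed by three paired
trials at onsets 500, 1,150 and 1,800 ms — a 650 ms envelope per trial
(300 ms CS, 350 ms recovery), back-to-back, the only uniform layout that
fits a probe plus three trials in the session. The US occupies the final
20 ms of each paired CS. Plasticity is frozen during the probe, making the
CR a pure read-out of the weights carried into the session; weights persist
across sessions while membrane states and noise are drawn fresh (each
session is its own run). Per-dentate-neuron Poisson noise (2,500 spikes/s,
1–2,500 ms, independent sources) runs throughout.

Rates are estimated with 10 ms rectangular bins, no smoothing
(population-averaged spikes/s; the simplest estimator consistent with the
grid, and the bin width is carried on the trace object). The read-outs,
all from the probe:

* **CR rate** $= 100\,\langle FR_{M1}\rangle / FR_{M1}^{max}$ over
  [0, 450] ms (control) or [0, 400] ms (ASD); an all-zero trace scores 0.
  The ratio is scale-invariant by construction.
* **Peak latency** = the time of the in-window M1 maximum over [0, 550] ms
  (control) or [0, 450] ms (ASD); ties average their bin centres, an
  all-zero trace yields a missing value excluded from group statistics.
* **Dentate statistics** = the in-window maximum of the pooled DNm+DNc
  trace and its (tie-averaged) time, over the same window as peak latency.

Groups of 15 subjects (seeds `base_seed + 1 … + 15`; default bases 1000
control, 2000 ASD, so the groups are independent) are compared per session
with the two-sided Mann-Whitney U test — exact for small untied samples,
normal approximation with continuity and tie correction otherwise — with no
multiple-comparison correction. Sidedness is not stated by the behavioural
sources, so the tests are two-sided with the direction reported separately.

## What the simulated cohort does and does not emulate

The synthetic subjects *are* the study conditions: all structural
parameters are fixed at their published values and the only between-subject
variation is the five uniform draws and the noise realizations. Because
every neuron within a population receives identical deterministic input
(the noise perturbations are ~0.003 mV per event), populations fire in
synchronous volleys. Three consequences worth knowing:

* Within-group variance of the read-outs is carried almost entirely by the
  cortical parameters ($I_e^{M1}$, $I_e^{mPFC}$, $\beta$, $\gamma$); the
  cerebellar stages are effectively deterministic per group. Group
  contrasts are therefore sharp (typically complete separation), which is
  why per-session p-values at 15 + 15 reach the test's floor rather than
  the specific intermediate values published for late sessions — those
  depend on unpublished implementation details and are not a reproduction
  target.
* The population-averaged binned *maximum* of a synchronously volleying
  population saturates at one spike per neuron per peak bin (100 spikes/s
  at 10 ms bins). Both groups reach this ceiling from session 1, so the
  dentate maximum-rate contrast between groups is a tie in this
  implementation: the −7 pA Purkinje→dentate weight (≤ 168 pA compound,
  2 ms decay) cannot gate the direct 500 pA CS drive, and its volleys are
  phase-locked to land just after the dentate cells have already fired.
  The dentate *mean* rate and peak timing do respond to the manipulations;
  the maximum does not. This is a documented limitation of the faithful
  parameter set, not a tunable.
* No trial-to-trial jitter of CS/US onsets, no conductance-based synapses,
  no thalamocortical loop, no neuromodulation: passing tests show the
  published circuit produces the published *directional* effects under its
  published parameters, not that the model generalises beyond them.

The headline behavioural effects do not depend on these simplifications:
the faster ASD acquisition arises because the shorter delays and smaller
Purkinje population let the dentate-motor volleys fill the (shorter) ASD
read-out window more completely from the first probe on, and the earlier
ASD peak follows directly from the halved sensory and motor transmission
delays. Prefrontal-motor potentiation accumulates over sessions (reaching
its cap after roughly five), adding the early mPFC-driven component to M1
that moves both groups' CR upward and their peak earlier as training
progresses — the modulatory role the architecture assigns to the cognitive
pathway. Motor-pathway Purkinje suppression completes in session 1, the
cognitive pathway's (starting at four times the initial weight, with a
kernel whose lobe only partially overlaps the trial's lag range) in session
2, preserving the observed ordering.

## Problem sizes used by the automated checks

The test suite simulates the full cohort once (15 + 15 subjects ×
10 sessions at dt = 0.1 ms) and reuses it across checks; directional
replication re-runs the two-group experiment at four further independent
base-seed pairs, at the same scale. (A dt = 1 ms smoke scale reproduces
the same qualitative behaviour an order of magnitude faster and is used
for the cheaper protocol-level checks.) Property checks (closed-form integration, rheobase,
plasticity oracles, Mann-Whitney enumeration and type-I calibration at
2,000 null replicates) run at single-neuron to few-subject scale. The
acceptance script simulates both groups from scratch at the full scale.
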