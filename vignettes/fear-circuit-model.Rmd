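---
title: "A firing-rate model of amygdala fear circuitry and its modulation by alcohol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A firing-rate model of amygdala fear circuitry and its modulation by alcohol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The circuit and its dynamics

`amyfear` simulates five neural populations of the amygdala fear circuit
with standard firing-rate (neural mass) dynamics:

* **LA** — lateral amygdala, receives the thalamic conditioned-stimulus
  (CS) input and inhibits itself;
* **BAf / BAe** — fear and extinction projection-neuron groups of the
  basal amygdala, mutually inhibiting; BAf receives LA excitation and the
  hippocampal context input, BAe receives the infralimbic-mPFC input;
* **CeAOn / CeAOff** — pro-fear and pro-extinction populations of the
  central amygdala, mutually inhibiting.  CeAOn receives BAf and LA
  excitation and is the behavioural output: its activation is the fear
  response.

Each population's normalized rate $U \in [0,1]$ follows

$$\tau \frac{dU}{dt} = F(\text{net input} + \eta) - U, \qquad
F(x) = \frac{1}{1 + e^{-\mathrm{Ex}\,(x - \mathrm{Th})}}$$

with a shared sigmoid ($\mathrm{Ex} = 10$, $\mathrm{Th} = 0.5$; one unit
of net input corresponds to roughly 100 pA of synaptic current) and time
constant $\tau = 0.05$ s.  The fixed weights default to the calibrated
naive values (LA$\to$BAf 0.49, BA mutual inhibition 0.13, LA
self-inhibition 1.0, BAf$\to$CeA and LA$\to$CeA 0.65, BAe$\to$CeA 0.98,
CeA mutual inhibition 1.5; all drives 0).

Integration is explicit Euler with a 15 ms step, 1000 steps per 15-s
stimulus period and 500 steps per 7.5-s intertrial relaxation.  $\eta$ is
Gaussian noise with mean 0.03 and standard deviation 0.1 (10% of the
maximal rate), drawn independently per population per step, *inside* the
argument of $F$ as the equations are written.  Euler updates are clamped
to $[0,1]$: $F$ is bounded in $(0,1)$, so any overshoot is a
discretisation artifact and clamping preserves the normalized-activity
contract.  Noise stays on during the intertrial interval (the circuit
resets by relaxation, not by re-initialisation).  With noise off,
trajectories are bit-reproducible, and trial statistics are insensitive
to halving or doubling the step and to trial durations from 5 to 60 s
(the test suite checks both).

## Plasticity

Three input synapses are plastic: thalamic$\to$LA, hippocampal$\to$BAf
and mPFC$\to$BAe.  After each trial the CeAOn readout — the mean CeAOn
rate over the final 10 integration steps of the stimulus period — is
compared with the binary US to form a prediction error
$\mathrm{ERR} = \mathrm{US} - U_\mathrm{CeAOn}$.  The fear-pathway
weights change by $\mathrm{ERR}\cdot\mathrm{US}\cdot\alpha\cdot
I_\mathrm{pre}\cdot U_\mathrm{post}$ and the extinction-pathway weight by
$-\mathrm{ERR}\cdot\alpha\cdot I_\mathrm{PFC}\cdot U_\mathrm{BAe}$, with
$\alpha = 1$; postsynaptic rates are the trial averages over the stimulus
period, matching the per-trial update granularity.  Updates are floored
at zero.  Two structural consequences, both tested: fear weights change
only in the presence of the US (extinction never depresses them —
extinction is new learning through the alternative mPFC$\to$BAe
pathway), and weight growth is Hebbian-gated, so it is very slow while
activities are near baseline and accelerates sharply once the positive
feedback between weight and postsynaptic activity ignites.

## The conditioning protocol

A session is 15 acquisition trials (CS + context on, US = 1), 10
home-cage rest trials (all inputs off, plasticity frozen) and 35
extinction trials (CS on, context off — a new context — plus the mPFC
input, US = 0).  Trial 25, the first post-rest trial, acts as fear
recall: LA reactivates at its acquisition level through the CS while BAf
stays low without its context input.  Trials-to-criterion are counted
1-based: acquisition is reached at the first trial whose trial-averaged
CeAOn exceeds the acquisition criterion, extinction at the first
extinction trial (counted from trial 25) whose trial-averaged CeAOn
falls to the extinction criterion or below.

Two alcohol overlays modify only fixed weights, applied for the whole
session: **acute** (BA inhibition 0.25, LA self-inhibition 1.5,
BAf$\to$CeA 0.4, BAe$\to$CeA 0.6, CeA inhibition 2.5) and **chronic**
(CeA inhibition 2.5, CeA drive $-0.5$, LA$\to$BAf 0.6).  Plasticity and
protocol are identical across conditions, so condition differences in
trial counts are predictions of the circuit changes alone.

## Calibration choices

Four constants are not determined by the published parameter tables and
were fixed once, using the naive condition only:

* **Input levels.** The CS input is 1.0.  The context input is 0.4: a
  diffuse contextual signal weaker than the discrete cue.  With context
  at full strength the context pathway out-competes the CS pathway —
  BAf saturates first, the prediction error collapses, the
  thalamic$\to$LA weight never potentiates, and the recall trial shows
  no fear, contradicting the reference behaviour in which recall shows
  acquisition-level LA activity and extinction then takes several
  trials.  With 0.4 the naive late-extinction rates settle at LA
  $\approx 0.8$, BAf $\approx 0.15$, BAe $\approx 0.9$, the reference
  working point of the reduced-system analysis.  The mPFC input is
  0.75, a deliberately weak initial drive of BAe; it sets the extinction
  timescale relative to acquisition.
* **Initial plastic weights.** 0.22 for all three pathways.  The update
  rule is multiplicative in the postsynaptic rate, so the time to
  ignition is set by the pre-training activity level; 0.22 keeps initial
  activities low (about 0.06) while producing ignition on the observed
  trial scale.  Exactly zero initial weights would stretch ignition to
  roughly twice as many trials.
* **Criterion thresholds.** Acquisition 0.80 of maximal CeAOn activity,
  extinction 0.10 ("near zero").  The acquisition criterion sits near
  the CeAOn plateau because the conditions differ mainly in how long
  CeAOn takes to climb from its first surge to its plateau; a criterion
  at the sigmoid midpoint cannot separate them.

With these fixed, 100-session naive ensembles give mean
trials-to-acquisition $\approx 7.1$ (SD 0.3) and trials-to-extinction
$\approx 8.0$ (SD 0.2), and the acute and chronic overlays — with no
further adjustment — give $\approx 9.7/13.1$ and $\approx 7.6/13.3$.
Both alcohol conditions slow both phases, acquisition is ordered acute >
chronic > naive, and chronic sessions show occasional post-extinction
reactivation events.  Two quantitative discrepancies remain and are
deliberate non-fixes: the model's acute and chronic extinction delays
are nearly equal rather than clearly ordered, and the late-extinction
CeAOff level is lowest under acute rather than chronic alcohol.  Both
trace to the acute overlay's strongly weakened BAe$\to$CeA coupling
(0.6) against a still-strong LA drive of CeAOn, which leaves the acute
CeA switch bistable trial-by-trial; we prefer reporting this property of
the printed parameter set to re-tuning it away.

## The reduced CeA subsystem

Late in extinction the BLA rates change slowly, so the CeA pair can be
studied with LA, BAf and BAe frozen (harvested from the last five
extinction trials of a full simulation, or supplied directly).  The two
nullclines are closed-form sigmoids, strictly decreasing in the opposing
variable; their intersections are located by sign-change bracketing plus
bisection on a 2000-point grid and classified by the eigenvalues of the
$2\times2$ Jacobian (zero real parts are conservatively reported as
unstable).  The test suite cross-checks the equilibria against an
exhaustive residual-minimising grid search at $10^{-3}$ resolution.  The
analytical robustness condition — CeA mutual inhibition must exceed
$(W_{\mathrm{BAf}\to\mathrm{CeA}} U_\mathrm{BAf} +
W_{\mathrm{LA}\to\mathrm{CeA}} U_\mathrm{LA} + \mathrm{Dr}_\mathrm{CeA}
- \mathrm{Th}) / U_\mathrm{Off}$ — evaluates to 0.8 at full activation
with naive weights, comfortably below the naive inhibition of 1.5;
negative CeA drive and weakened excitation shrink that margin under the
alcohol overlays.

## What the simulations do and do not show

The generator *is* the model: there is no external data, and ensembles
(default 100 sessions, seeds `base_seed ... base_seed + n - 1`)
characterise the noise-induced variability of an idealised protocol with
binary inputs, a single CS, one context per phase and trial-end
learning.  Passing tests therefore demonstrate internal consistency and
reproduction of the reference statistics, not fit to any animal data.
Renewal, reinstatement, spontaneous recovery, within-trial US timing,
explicit interneurons and conductance-based dynamics are out of scope.
Trial counts quoted above use the full 15 s / 7.5 s trial structure;
mechanistic unit tests run 5-s trials, inside the range where the
statistics are duration-invariant.
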