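---
title: "A spinal-circuit model of human quiet standing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spinal-circuit model of human quiet standing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nmstand)
```

## The model

`nmstand` simulates upright quiet stance as a closed loop between spinal
physiology and single-joint biomechanics. The body is a point-mass inverted
pendulum about the ankle (mass 60 kg excluding the feet, centre of mass
0.85 m above the joint, inertia $I = mh^2$), destabilised by gravity with
load stiffness $K_c = mgh \approx 500$ Nm/rad. Restoring torque comes from
three sources: a passive ankle stiffness of $0.65\,K_c$ with viscosity
5.81 Nm·s/rad, the small intrinsic viscoelasticity of the musculotendon
units, and the active torque of the triceps surae (soleus SO, medial and
lateral gastrocnemius MG/LG) against the tibialis anterior (TA), driven by
a spinal circuit.

The spinal controller contains type-specified motor neurons (S, FR, FF;
e.g. 800/50/50 for SO, 300/150/150 for MG) modelled as two-compartment
conductance-based neurons with stereotyped spike conductance transients and
a saturating afterhyperpolarisation, plus six pools of 350 point
interneurons (group-II excitatory, Ib inhibitory, and reciprocal Ia
inhibitory, for each side). Synapses follow a two-state kinetic scheme with
fixed-duration transmitter pulses; all synapses of one class on one target
form a saturating bank whose maximum conductance is the tabulated class
value. Motor axons conduct spikes over 0.80 m at type-specific velocities
(44–53 m/s).

Muscles are Hill-type: per-motor-unit activation is the spike train
filtered by a second-order critically damped system (time-to-peak 25–100 ms
by type) and passed through a smooth saturation tuned so each unit
plateaus at its tetanic rate; tetanic amplitudes grow 100-fold across the
recruitment-ordered pool. Slow (S) and fast (FR+FF) sums drive separate
contractile elements with fibre-type-specific force–length and
force–velocity curves, in parallel with an exponential-strain elastic
element and linear viscosity, in series with a toe-linear tendon through a
constant-thickness pinnation, with a small fibre mass for integrability.
Quartic polynomials give each muscle's length and moment arm versus ankle
angle.

Proprioception closes the loop: a bag1/bag2/chain intrafusal spindle model
(static and dynamic fusimotor drives; Ia output combines all three fibres
with partial occlusion, II output is static) and a tendon-organ model
(logarithmic static stage, 60 Hz and 4 N constants, followed by a
zero/pole transfer function discretised by the bilinear transform).
Receptor outputs recruit afferent bundles across a linear 0–50 Hz
threshold grid and are emitted as independent non-homogeneous gamma point
processes (order 6 by default). Descending drive is 400 homogeneous gamma
renewal processes at 50 Hz with shape 25 (ISI CV 20%).

Everything advances on one fixed-step RK4 clock (50 µs). A run clamps the
pendulum for 1 s while the neuromuscular system reaches steady state, then
releases it; a lean beyond 25° flags the run as fallen. Two circuit
variants are provided: `model2` is the complete circuit and `model1`
removes the reciprocal-inhibition pathway (antagonist Ia afferents via Ia
interneurons onto the triceps surae motor nucleus); the variants share
every other connection and random draw exactly.

## Parameters that matter, and their defaults

* `scale` (default 1; analyses here use 0.2): multiplies every pool and
  bundle size, preserving type proportions. Synaptic bank conductances are
  held fixed, so the mean drive per neuron is scale invariant; what grows
  at small scale is motor-unit torque granularity (roughly $1/\sqrt{N}$).
* `fusimotor_static` / `fusimotor_dynamic` (32 / 33.8 Hz-like units): set
  the spindle operating point; both carry Gaussian noise with variance 3%
  of the mean, realised as an Ornstein–Uhlenbeck process with a 100-ms
  correlation time (the variance is stated by the source of the model, the
  bandwidth is this package's choice).
* `g_descending` (1230 nS): the saturated descending synaptic bank per
  motor neuron, calibrated once so that the descending drive alone (all
  feedback off, pendulum locked) produces a basal torque of about 2% of
  the maximum torque — a stated property of the drive, not a fit to sway
  data.
* `spindle_gains` (1, 1, 1): multipliers on the three intrafusal
  afferent-potential gains.
* Spindle mounting: each muscle's upright operating fibre length is mapped
  onto the intrafusal model's rest length (triceps surae target 0.98,
  since those muscles shorten actively during stance; TA target 0.95,
  since it stays passive). Without this offset the fibre operating lengths
  implied by the tendon decomposition (1.04–1.14 optimal lengths) sit far
  above the spindle model's sensitive region, and no physiological gain
  setting yields both realistic stance rates (5–40 Hz) and enough
  positional feedback to stand.
* The passive ankle spring acts about the standing reference angle
  (`theta0_deg`, default 5° forward): it represents the incremental
  stiffness measured experimentally about the operating posture. This is
  also what makes the basal plantar-flexion torque at a 5° lean about 10%
  of maximum, as observed; a vertical-centred spring would imply only ~3%.

## Numerical choices

Single-rate RK4 at 50 µs for membrane, synaptic, muscle, receptor and
pendulum states, with synaptic conductances and activations held constant
within a step; spikes are detected as upward threshold crossings and
stamped at the end of the step. The fibre mass makes the muscle ODE
non-stiff at this step (natural frequencies ≲150 Hz, step stability margin
> 40×). Synapse banks use the exact piecewise-exponential solution of the
two-state kinetics with group-mean bookkeeping of pulse onsets/offsets
(exact for homogeneous banks). Activation filters use the closed-form
update of the critically damped system. The tendon-organ filter is three
bilinear first-order sections (cascading avoids the ill-conditioning of a
direct-form third-order filter at 20 kHz). The tendon toe–linear
transition is placed at 0.964 so the normalisation (unit force at unit
normalised length) holds exactly; static fibre equilibria are found by
bisection; degenerate pinnation (required $\sin\alpha \ge 1$) raises an
error rather than clamping.

Welch spectra use Hann windows, segment length one quarter of the record,
50% overlap, with the 50%-power frequency interpolated linearly on the
cumulative spectrum. The modal inter-recruitment interval uses 50-ms bins.
The passive-stiffness experiment reports the in-phase (real) part of the
cross-spectral impedance averaged over 0–1 Hz — the static component; the
quadrature part is viscous. The moment-based normality statistic used for
the sway histogram is implemented in-package (with the asymptotic
$\chi^2_2$ null), as is the Welch estimator.

## What the simulations do and do not show

Runs at pool scale 0.2 with seeds 1–3 complete 30 s for both variants;
with the controller off the pendulum falls within ~2 s, and the passive
contribution of the musculotendon units alone is ~7% of $K_c$. The loop
reproduces the qualitative physiology: stable sway about a forward lean,
zero-lag COM–COP correlation, muscle activity leading sway by 100–250 ms,
continuous soleus activity with intermittent gastrocnemius recruitment at
~0.5-s mean inter-recruitment intervals, and a higher share of
"paradoxical" (negatively COM-correlated) soleus fibre-length windows when
reciprocal inhibition is present.

Quantitatively, the simulated sway is faster and larger than the human
force-plate reference values: the centre-of-pressure carries a 1–5 Hz
component produced by the recruitment limit cycle of the loop, which
inflates the mean velocity and the 50%-power frequency well above the
reference bands, and shortens the EMG-to-sway lead times. Part of this is
desk scale (torque granularity at scale 0.2 is ~2.2× the full-scale
value), and part is the loop's phase margin at 2–4 Hz, which depends on
unprinted quantities (twitch time constants, interneuron excitability,
intrafusal gains) that were fixed once from physiological ranges and not
iterated against the reference values. Conclusions about absolute
posturographic magnitudes should not be drawn from the reduced-scale
defaults; the structure of the loop, the receptor models, the analysis
battery, and the variant contrast (reciprocal inhibition) are the load-
bearing parts.

The synthetic protocol also idealises real data in ways that matter for
interpretation: no vestibular/visual/cutaneous input, a single rigid link,
stationary descending statistics, and surface EMG without volume
conduction. Passing tests therefore demonstrate internal consistency and
faithfulness to the modelled physiology, not validity for any particular
subject population.

## Problem sizes used in the packaged analyses

The packaged tests and the reproduction script use: 30-s closed-loop runs
at pool scale 0.2 (three seeds per variant), a 60-s passive-stiffness
record analysed at 200 Hz, and a 5-s locked basal-drive run at scale 0.2.
These sizes were chosen as the smallest at which the protocol statistics
(three-run means, 21 correlation windows, hundreds of inter-recruitment
intervals) remain well defined.
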