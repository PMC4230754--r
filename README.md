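# nmstand — a biologically based neuromusculoskeletal model of quiet standing

`nmstand` is for motor-control and posturography researchers who want to ask
*mechanistic* questions about upright stance: can a spinal circuit alone —
motor-neuron pools, interneurons, muscle proprioceptors — stabilise the body,
and what recruitment patterns emerge when it does? Instead of an abstract
PD-controller, the package closes the loop with explicit physiology:

* **Body**: a point-mass inverted pendulum about the ankle,
  `I θ̈ = m g h sin θ − T_a`, with `m = 60 kg`, `h = 0.85 m`, critical
  (load) stiffness `K_c = m g h ≈ 500.3 Nm/rad`, passive ankle stiffness
  `0.65 K_c` and viscosity `5.81 Nm·s/rad` about the standing posture.
* **Muscles**: Hill-type musculotendon units for soleus (SO), medial and
  lateral gastrocnemius (MG, LG) and tibialis anterior (TA) — slow/fast
  contractile elements with force–length/velocity curves, exponential-strain
  parallel elasticity, toe-linear tendon, constant-thickness pinnation, and
  quartic length/moment-arm polynomials in the ankle angle.
* **Spinal circuit**: type-specified (S/FR/FF) two-compartment motor neurons
  (SO 800/50/50, MG 300/150/150, LG 130/65/65, TA 250/50/50), six pools of
  350 interneurons (group-II excitatory, Ib inhibitory, reciprocal Ia
  inhibitory), kinetic synapses with tabulated connectivity fractions and
  saturating bank conductances, and 400 descending gamma-process axons
  (50 Hz, shape 25).
* **Proprioceptors**: a bag1/bag2/chain muscle-spindle model with static and
  dynamic fusimotor drives (Ia and II outputs), a Golgi tendon organ model
  (logarithmic statics, 60 Hz / 4 N, plus transfer-function dynamics), a
  linear 0–50 Hz afferent recruitment law, and non-homogeneous gamma spike
  encoders.
* **Analyses**: the standard posturography/motor-unit battery — COP RMS,
  mean velocity and 50%-power frequency, COM–COP and COP–EMG
  cross-correlations, activation ratios, inter-recruitment intervals,
  recruitment phase plots, 3-s windowed fibre-length/COM correlations, and a
  Jarque–Bera bimodality screen of the COM histogram.

Two circuit variants are built in: `model2` (complete) and `model1`
(reciprocal inhibition from TA Ia afferents onto the triceps surae removed),
sharing every other connection and random draw, for clean pathway contrasts.

## Worked example

```r
library(nmstand)

cfg <- stand_config(variant = "model2", duration_s = 30, scale = 0.2, seed = 1)
r <- run_simulation(cfg)
print(r)
#> Quiet-stance simulation (model2), 30 s at scale 0.2
#>   status: completed
#>   mean lean 4.09 deg, mean torque -40.5 Nm
#>   spikes: 306869 neuronal, 203432 afferent

cop <- preprocess_series(r$series$x_cop * 1000, 2000)   # mm, trimmed+detrended
com <- preprocess_series(r$series$x_com * 1000, 2000)
cop_metrics(cop)           # list(rms = 18.4, mv = 216.5, f50 = 0.91)
xcorr_peak(com, cop)       # rho 0.75 at lag -2 ms (zero-lag COM-COP peak)

lf <- preprocess_series(r$muscles$SO$L_f, 2000)
windowed_length_correlation(com, lf)   # 2 orthodox vs 5 "paradoxical" windows
```

The run stands for the full 30 s leaning ~4° forward with a plantar-flexion
torque of ~−40 Nm (the negative sign is the plantar-flexion convention);
COM and COP are highly correlated at zero lag; and in this complete-circuit
variant most 3-s windows show the "paradoxical" negative correlation between
soleus fibre length and body sway. Running the same seed with
`variant = "model1"` shifts those windows mostly to the positive ("orthodox")
side — the packaged acceptance tests quantify that contrast with a
chi-square test. A controller-off run
(`stand_config(controller = FALSE)`) falls within ~2 s, because the passive
ankle stiffness (0.65 K_c plus only ~7% of K_c from the musculotendon units)
cannot stabilise the load.

A thin command-line front end is installed with the package
(`inst/exec/nmstand`): `simulate`, `passive-stiffness`, `basal-check` and
`analyze` subcommands over the same functions.

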