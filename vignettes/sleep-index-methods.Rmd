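---
title: "The thigh-accelerometer sleep index: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The thigh-accelerometer sleep index: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thighsleep)
```

## The model

The package estimates nocturnal sleep from a single thigh-worn
accelerometer using a per-second recursive state variable, the sleep
index

$$S_n = \min\!\left(e,\; e^{-1/\tau} S_{n-1} + k A_n\right),$$

where $A_n$ is the mean band-pass-filtered acceleration vector magnitude
of second $n$ (in g), $\tau$ the decay time constant and $k$ the
movement gain. The construction is in the Cole–Kripke tradition of
weighted-activity sleep scoring, reduced to its recursive essence: an
exponentially weighted memory of recent movement. A second is classified
wake when $S_n \ge 1$ and sleep when $S_n < 1$.

Three properties follow directly and are pinned by tests:

* **Clamp.** With the index capped at $e$, a sustained movement episode
  saturates the state. From saturation with no further movement,
  $S_n = e \cdot e^{-n/\tau}$ crosses the threshold 1 exactly at
  $n = \tau$: sleep onset is declared $\tau$ seconds after a full
  awakening, by design. The cap is stored as `exp(1)` exactly; the
  commonly quoted "2.71" is this constant truncated to two decimals,
  and storing the truncation instead would shift the onset delay from
  1111 s to 1107 s and break the $\tau$-delay identity.
* **Steady state.** A constant activity $A$ (no clamp) drives the index
  to $kA/(1 - e^{-1/\tau})$, the geometric-series limit; with the
  default parameters any sustained $A \gtrsim 4.7$ mg keeps the wearer
  "awake". This closed form doubles as an independent test oracle for
  the recursion.
* **Monotone decay.** With $A_n \equiv 0$ the index is strictly
  decreasing and positive, so classifications in quiescence are a single
  sleep onset, never flicker.

The equality case $S_n = 1$ is not specified by the published rule
("above 1 awake, below 1 asleep"); the package resolves it to wake, the
conservative direction for a sleep estimator. It is reachable exactly
(e.g. $S_\tau = 1$ from the clamp under zero activity), so the tie-break
matters for the onset-delay arithmetic.

## Preprocessing

Raw recordings at any rate from 25 Hz upward are linearly interpolated
onto a 30 Hz grid (with a zero-phase Butterworth low-pass guard at 90 %
of the target Nyquist when downsampling). Each axis is then band-pass
filtered 0.5–10 Hz with a 4th-order-per-edge Butterworth applied
forward–backward, the vector magnitude is taken, values below 0.02 g
are gated to zero, and the remainder is averaged into whole seconds.

Design notes, in the order they bit:

* **Filter-then-norm.** The norm of the raw axes is dominated by the
  1 g gravity component; the per-second activity is therefore the
  magnitude of the *filtered* axes, with each axis mean-removed first so
  DC is rejected exactly rather than to filter precision.
* **Zero phase.** Forward–backward filtering avoids shifting movement
  bursts relative to the 30-s PSG epoch grid; the effective amplitude
  response is the squared Butterworth magnitude, which is what the
  filter-gain tests assert (on the bilinear-prewarped frequency axis).
* **Padding.** `signal::filtfilt` does not extend the signal, which
  leaves large edge transients; the package pads with an odd reflection
  (up to 512 samples) before filtering and trims it afterwards.
* **Edge trim.** The first and last 2 s of the activity series are
  zeroed rather than dropped: the transient cannot then masquerade as
  movement, while the series keeps its 1 Hz alignment with the
  recording start and hence with the epoch grid.
* **Gate before averaging.** The 0.02 g noise gate applies to the
  per-sample magnitude before the per-second mean, so sparse noise
  cannot accumulate into a nonzero $A_n$; a motionless lying recording
  yields $A_n \equiv 0$ identically.

## Post-processing

* **Short-bout removal.** State bouts shorter than 10 s are removed.
  This is implemented as iterative run-length merging — the shortest
  offending run (earliest on ties) is relabelled to match its
  neighbours until every maximal run lasts ≥ 10 s — rather than as a
  windowed sliding median. A 19-s sliding median with replicated edges,
  the textbook realisation, provably admits fixpoints with sub-10-s
  runs at the series edges (e.g. one wake second followed by sleep
  survives), so it cannot meet the stated post-condition; run-length
  merging meets it exactly and preserves every run already ≥ 10 s in
  place.
* **Awakening back-shift.** The index needs time to climb above
  threshold once movement resumes, so each detected awakening is moved
  2 min earlier: at every sleep→wake transition the trailing 120 s of
  the preceding sleep bout are relabelled wake, clipped at the bout
  start. The shift is applied simultaneously at all transitions of the
  cleaned series, after bout removal and before the lying restriction —
  cleaning first prevents 2-min penalties from spurious 1-s awakenings.
  The back-shift is applied only to the algorithm's own labels, never to
  the PSG reference.
* **Lying restriction.** Sleep is only trusted while recumbent: seconds
  outside lying bouts of at least 15 min are forced to wake. The
  built-in detector is deliberately simple plumbing — a 5-s moving
  average per axis, then the angle between the longitudinal (x) axis
  and the measured gravity vector, thresholded at 45° — because the
  surrounding study design assumes a dedicated posture classifier;
  user-supplied bout files or a whole-recording flag override it. The
  15 min bound is implemented as ≥ 900 s (the open-interval reading
  differs only on a measure-zero boundary).
* **Epoching.** The secondwise labels are reduced to 30-s epochs by
  majority vote, ties to wake, trailing partial epochs dropped — the
  mode filter that matches PSG scoring resolution.

## Sleep variables and agreement statistics

The six per-night variables follow the standard definitions: with $t_0$
the analysis-window start, sleep onset the first sleep label and the
last awakening the onset of the terminal wake run (the window end if the
night ends asleep), the sleep interval is onset→last awakening, TST the
sleep within $[t_0,$ last awakening$)$, latency $t_0$→onset, WASO the
wake inside the interval, efficiency $100\cdot$TST$/$(last awakening
$- t_0)$, and the awakening index counts wake bouts *strictly longer*
than 10 s per hour of sleep interval. Two conventions were open and are
fixed here: the index denominator is the sleep interval (the period in
which awakenings are defined), and "longer than 10 s" is read strictly,
so a 10.0 s bout does not count. `sleep_interval = TST + WASO` holds
exactly by construction and is fuzz-tested.

Agreement uses Bland–Altman differences in the direction algorithm −
PSG (underestimation shows as negative bias), sample SD throughout,
LoA $= $ bias $\pm 1.96\,$SD, the LoA range (LoAR) as the precision
summary, t-based CIs for the bias and the classic
SE $= $ SD$\sqrt{3/n}$ approximation for the LoA CIs, and Pearson
correlation with Fisher-z intervals (via `stats::cor.test`). The
implementation is checked against independently coded textbook formulas
to 1e-9. The outlier sensitivity analysis excludes nights whose
*reference* TST lies beyond 2 SD of the cohort mean and recomputes the
full table on the remainder.

Parameter calibration is an exhaustive grid search maximising cohort
mean sensitivity + mean specificity (sleep as positive class), with the
per-second activity and lying bouts cached per recording since neither
depends on $(\tau, k)$; ties resolve to the smaller $\tau$, then the
smaller $k$. Whether the historical procedure summed per-recording
statistics or pooled epochs is ambiguous; per-recording averaging is the
default and pooling is available behind a flag.

## The synthetic-data generator

The simulator provides ground-truthed nights so the full chain is
testable without device data. A night is an alternating wake/sleep bout
sequence (exponential durations — memoryless, the simplest defensible
run-length law) starting with a fixed initial wake period, over which
the tri-axial signal is built as constant gravity along the lying
orientation + Gaussian sensor noise + Poisson-timed movement bursts:
2–8 Hz tapered oscillations (inside the analysis band by construction)
of 1–5 s during wake and 1–3 s during sleep, in random directions.
Cohorts jitter the bout and burst parameters log-normally per night,
each night on its own seeded RNG stream.

Defaults were fixed a priori from the physiology of a healthy adult
laboratory night and the cohort tables of the validation literature: an
8 h recording; 10 min initial wake (the cohort PSG mean latency); mean
sleep bouts of 4 h with mean 5-min wake bouts, i.e. one to two
consolidated *behavioural* awakenings per night — consistent with the
algorithm-visible awakening index of ~0.5/h, since the many brief
cortical arousals PSG scores involve no thigh movement and are invisible
to any actigraph; 6 bursts/min at 0.4 g while awake; 0.5 twitches/min at
0.05 g (postural shifts) while asleep; 5 mg noise, safely under the
0.02 g gate; a 25 Hz device with the thigh horizontal. Under these
conditions the expected sensitivity is analytically
$\approx 1 - (\text{onsets} \times \tau)/\text{TST} \approx 0.87$ and
specificity well above 0.5, which the 20-night regression test confirms
(measured ≈ 0.91/0.87).

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: sleep staging and cortical arousals without
movement, periodic limb movements and other movement disorders, non-wear
and device displacement, posture changes between lying orientations,
clock drift between devices, and the scorer variability of real PSG.
The published cohort statistics (sensitivity 0.84, specificity 0.55,
LoAR 130/233 min) are properties of real nights and are *not*
reproduced by simulation; the package's acceptance checks are instead
the analytic constants of the recursion and the agreement arithmetic of
the printed limits.

## Numerical and scale choices

Everything is deterministic: the pipeline has no hidden state and
repeated runs are bit-identical; all simulator randomness derives from
explicit seeds. Test problem sizes were chosen to exercise the
asymptotics while keeping the suite quick: 1000 × 120-s series for the
recursion/closed-form equivalence (1e-9), 10 000 random binary
sequences for the bout-cleaning invariant, 1000 random series for the
metric identities, and a 20-night default cohort for the end-to-end
operating point. The closed-form oracle is evaluated only on clamp-free
trajectories, where it is exact.

## Limitations

The method estimates behavioural quiescence, not neurophysiological
sleep: quiet wakefulness after the onset delay is scored as sleep
(bounding specificity), every sleep onset costs up to $\tau$ of
detection delay (biasing TST and latency), and sleep-quality variables
(WASO, awakening index) inherit both effects. It is suited to
group-level sleep-duration estimation alongside activity measurement,
not to individual-level sleep-quality assessment.
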