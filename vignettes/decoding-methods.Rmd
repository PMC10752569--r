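---
title: "Decoding joint torque from motor-unit activity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding joint torque from motor-unit activity: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mudecode)
```

## The problem

Proportional myoelectric control of assistive devices needs a continuous
estimate of intended joint torque. The conventional input is the surface
EMG amplitude (aEMG): the RMS envelope of the interference signal,
normalized to a maximum-voluntary-contraction (MVC) reference and regressed
against measured torque. Because surface EMG is a superposition of motor
unit action potentials (MUAPs) of mixed polarity, its amplitude grows
sublinearly and noisily with neural drive (amplitude cancellation), which
limits aEMG decoding.

EMG decomposition recovers individual motor-unit (MU) spike trains from
the interference signal, enabling two MU-based alternatives:

* **Neural drive (ND)** — the smoothed firing rates $FR_i(t)$ of the
  retained units enter a multiple linear regression
  $\tau(t) = \sum_i a_i\,FR_i(t) + b$.
* **MUDrive** — each retained unit's spike train is convolved with a
  modeled force twitch, the gain-weighted twitch trains are summed into a
  modeled-force signal, and a single linear regression maps it to torque.

This package implements all three decoders, their shared signal-processing
chain, spike-triggered-averaging (STA) validation of decomposed units,
genetic-algorithm (GA) fitting of the twitch-model pool parameters,
Monte-Carlo sensitivity analysis, optimization refinement, and a
cross-validated cohort evaluation — together with a synthetic motor-unit
pool generator that provides ground truth for every stage.

## The twitch model

A unit's twitch is parameterized by peak force $P$, rise time $T_r$ and
half-relaxation time $T_{hr}$:

$$
f(t) = \begin{cases}
P\,\dfrac{t}{T_r}\,e^{\,1 - t/T_r} & t \le T_r\\[4pt]
P\,2^{-(t - T_r)/T_{hr}} & t > T_r
\end{cases}
$$

so $f(0) = 0$, the unique maximum $P$ occurs exactly at $T_r$, and the
force has halved exactly $T_{hr}$ after the peak. The sampled waveform is
truncated once it decays below $10^{-4}P$. Only these contract properties
are relied on downstream; any functional form satisfying them could be
substituted.

At short inter-spike intervals twitches fuse nonlinearly. Each spike's
contribution is scaled by a sigmoidal gain of the normalized stimulus rate
$x = T_r/\mathrm{ISI}$: unity for $x \le 0.4$ and
$\frac{S(x)/x}{S(0.4)/0.4}$ with $S(x) = 1 - e^{-2x^3}$ above the knee
(continuous at $x = 0.4$; the first spike of a train has gain 1). The gain
rises above one in the fusion region before decaying at tetanic rates —
the classic catch-like enhancement of force summation.

Pool parameters, not per-unit parameters, are fitted: the six scalars
$(P_{min}{=}1, P_{max}, T_{r,min}, T_{r,max}, T_{hr,min}, T_{hr,max})$
define ranges, and each retained unit receives its triplet by linear
rescaling of its recruitment threshold (RT) within the retained set's RT
range — the size principle: later-recruited units get larger, slower
twitches. The RT of a unit is the EMG amplitude (in %MVC) in a 200-ms
window centered at the first time its windowed firing rate exceeds 5 Hz.

The five free scalars are optimized inside a fixed physiologic constraint
box (`constraint_box()`): $P_{max} \in [1.1, 150]$ (arb.),
$T_{r,min} \in [30, 110]$ ms, $T_{r,max} \in [150, 240]$ ms,
$T_{hr,min} \in [15, 60]$ ms, $T_{hr,max} \in [110, 140]$ ms.

## Signal processing

All features live on one 10 Hz grid of 0.5-s window centers advanced in
0.1-s steps (half-open windows $[c - w/2, c + w/2)$). Torque is
DC-corrected (mean of the first second), low-pass filtered at 2 Hz
(4th-order Butterworth, zero-phase) and window-averaged. EMG is band-pass
filtered 20–450 Hz (cascade of 4th-order high- and low-pass Butterworth
sections applied zero-phase; the cascade avoids the numerical
ill-conditioning of a single transfer-function band-pass at a 0.018
normalized low edge). The aEMG feature is the windowed RMS normalized to
the MVC reference (largest sliding 0.5-s RMS of a maximal contraction).
Firing rates are windowed spike counts divided by the window length. The
MUDrive signal is window-averaged (the same operator as the torque
reference; it is a nonnegative smooth force signal, so mean and RMS nearly
coincide).

Amplitude-like features are then smoothed by a scalar random-walk Kalman
filter (identity state and observation). Default noise variances are
proportional to the series variance — process $10^{-2}\sigma^2$,
measurement $10^{-1}\sigma^2$ — giving a steady-state gain of about 0.27
per 0.1-s step (time constant ≈ 0.3 s). This suppresses envelope noise
without distorting the 2-s torque ramps; a ten-fold smaller process
variance (gain ≈ 0.1, time constant ≈ 1 s) was tested and rejected because
its lag exceeds the ±0.5-s alignment search and its shape distortion
dominates every decoder's error. Scale equivariance
(smooth$(ax) = a\,$smooth$(x)$) follows from the variance-proportional
defaults.

Before regression each input is aligned to the torque reference by the
Pearson-correlation-maximizing lag on the 0.1-s grid (±0.5 s search, ties
toward zero lag); for the rate-based decoders one common lag is estimated
from the summed rate. The lag is estimated on the training fold and reused
on the test fold.

## Unit validation and refinement

Decomposed units pass two STA gates. *Accuracy*: the whole-trial STA
(80-ms windows centered at each discharge, edge-clipped discharges
skipped) must match the decomposed MUAP template with squared peak
normalized cross-correlation $R^2 > 0.6$. The template is zero-padded
(centered) to the STA length and the correlation is normalized over the
full vectors with the alignment search restricted to ±10 ms; normalizing
only over a sliding overlap was tested and rejected because band-limited
noise then matches a short template somewhere, letting units with random
discharge times pass. *Stability*: STAs recomputed in 8-s windows stepped
by 4 s (segments with at least 4 usable discharges) must have a
peak-to-peak amplitude CV below 0.5. Both gates are invariant to a global
EMG gain.

Accepted units are ranked by the $R^2$ of a single-unit regression of
torque on their smoothed rate; the best 10 are retained (all, if fewer),
with ties broken by unit id. ND and MUDrive share this retained set.

## Optimization, sensitivity, refinement

The GA is real-coded over the masked-on parameters inside the constraint
box: tournament selection (size 3), BLX-0.5 crossover, Gaussian mutation
(SD 10% of each box range), elitism 1, early stop after 10 stagnant
generations (<1e-6 improvement); defaults population 30 × 40 generations,
the cohort evaluation uses 15 × 20. The candidate cost is the *training*
RMSE of the full MUDrive fit (regression refit per candidate, so the cost
is well defined). The box midpoint is always injected into generation 0,
so the search never returns worse than the no-optimization baseline.
Infeasible combinations (a minimum at or above its maximum) get infinite
cost.

One-at-a-time Monte-Carlo sensitivity holds four parameters at their
optimized values and draws the fifth uniformly over its box range,
recording the test-fold RMSE per draw (test rather than training RMSE,
since model performance elsewhere means held-out error). Iterations
continue until at least 1,000 have run and the running SD over all
iterations has changed by less than $10^{-4}$ across the final 50
(cap 20,000); infeasible draws are redrawn without counting. Parameters
are ranked by converged SD, ties broken by the canonical order
`ga_parameter_order()`.

Refinement masks on the $k$ most sensitive parameters and fixes the rest
at the constraint-box midpoints. `refinement_sweep()` warm-starts each
stage with the previous optimum (feasible because the newly freed
parameter sat at its midpoint), making the best cost nonincreasing in $k$
by construction; `refine_and_time()` runs a single independent stage.

## Evaluation

Each two-trapezoid trial is split at the midpoint of the inter-trapezoid
rest into two folds; models (including the GA for MUDrive) are trained on
one fold and scored by RMSE on the other, then the folds swap. Nothing
from the held-out fold — samples, firings, alignment lag, GA cost — enters
training. The cohort evaluation simulates virtual subjects (distinct pool
realizations and decomposition yields), runs all three decoders at 20 and
35 %MVC targets, and compares per-subject mean RMSE with paired t-tests,
Bonferroni correction (×3) and a paired Cohen's d
($\bar d / \mathrm{SD}(d)$). If the SD of paired differences is zero the
comparison is flagged degenerate (identical columns: $t = 0, p = 1$;
constant shift: $p = 0$).

## The synthetic generator

The generator emulates isometric trapezoid-tracking trials: a 5-s
quiescent lead-in, 10 %MVC/s ramps to the target (20 or 35 %MVC), 12-s
holds, 10-s rests. A physiological pool of `n_units` (default 100) motor
units has recruitment thresholds on an exponential ladder from `rt_min`
(default 2 %MVC) spanning a ratio of `recruitment_range` (default 30, so
thresholds reach 60 %MVC and submaximal targets recruit only part of the
pool). Rate coding is linear above threshold (8 Hz at recruitment,
0.7 Hz/%MVC gain, 35 Hz saturation) with Gaussian ISI jitter (CV 0.2,
2-ms floor). Ground-truth twitch parameters follow the same size-principle
rescaling the decoder uses, with true pool ranges spanning most of the
physiologic box ($P_{max} = 100$, $T_r \in [30, 240]$ ms,
$T_{hr} \in [15, 140]$ ms). EMG is the superposition of biphasic MUAPs
(first derivative of a Gaussian, 15 ms, amplitude proportional to RT) at
the true discharge times plus white noise at 20 dB SNR — so amplitude
cancellation emerges naturally. Torque is the gain-weighted twitch
superposition of the whole pool plus white noise. The MVC reference is
itself simulated (3 s at 100 %MVC drive through the same pool).

Two aspects emulate the measurement process rather than the physiology:

* **Decomposition yield.** Surface decomposition recovers a minority of
  the active pool, biased toward large units. The generator marks a
  size-biased subset (`n_decomposed`, default 25; sampling probability
  proportional to squared MUAP amplitude among units with at least 20
  discharges) as "decomposed"; only these are visible to the decoders,
  while the whole pool generates EMG and torque. Exposing the entire pool
  instead makes the ND regression unrealistically exact.
* **Decomposition error.** Observed spike trains are corrupted copies of
  the true trains: each discharge is missed with probability `miss_rate`
  (default 0.10) and spurious discharges are inserted at `false_rate`
  (default 0.10) of the true count — the order of error reported for
  surface decomposition at moderate-to-high contraction levels. The error
  destabilizes the ten-coefficient ND fit on nearly collinear rates more
  than the single-scale MUDrive fit, which is the realistic mechanism
  behind the MU-based method ordering.

What the generator does **not** model: volume conduction and electrode
geometry, MU synchronization and common-drive fluctuations beyond the
shared excitation profile, fatigue, tracking error around the target
profile, and antagonist co-contraction. Passing tests therefore show that
the pipeline recovers the built-in structure of this idealized world, not
that it would reach the same absolute errors on human data.

## Identifiability of the twitch parameters

Two genuine findings from the synthetic world are worth recording. First,
the cost surface of the full default pipeline is nearly flat in
$T_{r,min}$: the twitch area grows with $T_r$ while the fusion gain
shrinks with it, so a unit's net force gain is insensitive to $T_r$ at
fused firing rates; window smoothing removes most residual shape
information. Second, estimated RTs (EMG %MVC at recruitment) are a
nonlinearly warped version of the drive at recruitment, which shifts the
rescaling and biases the optimum away from the generating values. The
parameter-recovery demonstration therefore uses an identifiable
construction: a fully observed 12-unit pool whose RTs (2–16 %MVC) are all
recruited at the 20 %MVC target, sub-knee firing rates (6–8 Hz) so the
fusion gain is inert, known thresholds, and near-identity Kalman settings.
Under it the cost surface is sharply unimodal at the true value and the
one-parameter GA recovers $T_{r,min}$ to within 1 ms.

Relatedly, because the rescaling normalizes RTs within the *retained*
set, the top retained unit always receives the maximum parameters, which
keeps $T_{r,max}$ influential on generic bundles. The minimum-parameter
dominance expected from low-threshold-skewed recruitment appears clearly
on a heavily skewed pool (25 units on an exponential ladder spanning a
100× threshold range at sub-knee rates, known thresholds, near-uniform
twitch amplitudes): there both minimum parameters rank above both maximum
parameters, with $T_{r,min}$ by far the most sensitive and $P_{max}$
between the two groups.

## Problem sizes and runtime choices

The packaged study conditions are sized for a workstation run: 8 virtual
subjects × 2 target levels × 1 two-trapezoid trial, GA population 15 × 20
generations per training fold inside the cohort (the standalone default is
30 × 40), Monte-Carlo sensitivity at the 1,000-iteration convergence
minimum, and recovery/refinement experiments over 3–5 seeds. All
randomness flows from explicit integer seeds; identical configuration and
seed give bit-identical bundles, optimizations and reports.

## Limitations

Absolute RMSE values depend on the arbitrary synthetic torque scale and
are not comparable to dynamometer measurements; only orderings, effect
sizes and mechanisms are meaningful. The two-fold split follows the
two-trapezoid trial design, so fold RMSEs are correlated within a trial.
The GA is stochastic: different seeds give slightly different bounds with
near-identical cost, which is why determinism is guaranteed only at fixed
seeds. The mixed-effects omnibus analysis of a full factorial design is
out of scope; the package reports descriptive summaries and paired
post-hoc tests only.
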