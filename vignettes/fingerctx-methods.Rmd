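---
title: "Models and methods behind fingerctx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fingerctx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

A kinematic brain-machine interface (BMI) for finger control is trained in
one physical context — a manipulandum with no added load — and then used
in another: torsional springs resisting flexion, a 23° wrist flexion that
shortens the finger flexors, rubber bands, or springs and wrist flexion
combined. These alterations change the muscle activation required for the
same finger movements drastically (flexors roughly double their
activation against springs) while changing the kinematics themselves very
little. `fingerctx` implements the full analysis chain for asking what
such context changes do to intracortical decoding: per-channel tuning and
its context modulation, offline cross-context generalization of linear
decoders, closed-loop Kalman-filter control with ReFIT retraining, and
population-level geometry (per-context PCA manifolds, principal angles,
demixed PCA).

Because every stage must be testable without recorded monkey data, the
package's first-class citizen is a synthetic session generator with
planted, recoverable structure. All statistical claims the test suite
makes are claims about recovery of that planted structure.

# The synthetic session model

## Task and kinematics

Sessions follow a center-out-and-back protocol: every other target sits at
the 50% center of the flexion range; out-targets at ±40% for the 1-DOF
task (both finger groups yoked) or at 20/30/40% combinations for 2-DOF.
Targets occupy 15% of the range of motion; holds are 750 ms
(manipulandum) or 500 ms (online); the center target is re-presented after
any failed trial, and context blocks of 175–350 trials alternate.
Movements are minimum-jerk trajectories (smooth, single-peaked speed
profiles; peak speed \(15A/8T\) for amplitude \(A\) and duration \(T\)),
with a jittered reaction time. Any smooth unimodal speed profile would
serve; minimum jerk is simply the conventional choice.

## Muscle activation

Eight EMG channels are simulated, four finger flexors and four extensors.
Per muscle \(m\) with weight \(w_m\), flexion velocity \(v\) (%/s), and
context gains \(g_F, g_E\) and co-contraction gain \(g_C\):

\[
\mathrm{flexor}_m = b + g_F\, w_m \, [v]_+ / 100,\qquad
\mathrm{extensor}_m = b + g_E\, w_m \, [-v]_+ / 100 + g_C [v]_+ / 100 .
\]

The default gains are the study conditions: spring \(g_F = 1.92,
g_E = 0.92\); wrist \(g_F = 1.53, g_E = 0.68\); normal gains are 1 by
definition. The rubber-band context is a stronger spring (the band adds
16.5 N to full flexion against the spring's 9.5 N), set once to
\(g_F = 2.5, g_E = 0.85\); the combined context multiplies the spring and
wrist gains. Co-contraction (\(g_C > 0\) for spring-like contexts) raises
extensor activation during resisted flexion. Raw 10 kHz EMG, when
requested, is envelope-modulated 100–500 Hz band-limited noise whose
binned mean absolute value recovers the envelope up to a uniform factor
(every analysis of muscle activation is ratio-based, so a common factor is
irrelevant).

## Latent structure and neural observation

Sixteen latents drive 96 channels through a fixed loading matrix, split
into four groups: condition-independent (trial-phase profiles and
unsigned speed), target (signed position and velocity profiles per finger
group, with lagged copies), context, and target-by-context interaction.

The context latents are the package's central modelling commitment. They
are time-shifted copies of a single signed *effort shift*

\[
e(t) = \Delta\mathrm{flexor}(t) - \Delta\mathrm{extensor}(t),
\]

the difference between each muscle group's envelope and its normal-context
counterpart. \(e\) is positive both when flexion requires more activation
than normal and when extension requires less, so one population direction
tracks required muscle activation across contexts — and it is identically
zero in the normal context. Because the latent is built from the muscle
envelopes rather than from the gains directly, the correlation between
the leading context component and active-muscle activation that the
geometry module reports is an emergent, recoverable property of the
construction, not a hard-coded output.

Three choices about the loading matrix matter for recovery:

* A configurable fraction of channels (default 60%) carries context
  loading at all; the rest are context-blind with exact zeros.
* Within the context-loaded channels, the context/interaction columns are
  orthogonalized to the movement-coding columns, so the context shift
  occupies new population directions (this is also what the well-aligned
  off-context manifolds in the principal-angle analysis presuppose).
* The shared effort direction has a per-channel magnitude floor. Without
  it, continuous Gaussian loadings leave some "modulated" channels with
  arbitrarily small realized effects and ground truth becomes
  ill-defined; with the floor, every planted channel carries a
  recoverable effect. Ground truth is nevertheless recorded functionally:
  a channel counts as context-modulated when its realized context drive
  is at least 10% of its total drive SD.

Channel drive is `baseline + loading %*% latents + noise` with iid
Gaussian noise (default SD 0.5) added before rectification; the
per-millisecond SBP value is the rectified drive (with a raw 2 kHz sample
count of 2), and threshold crossings are an inhomogeneous Poisson process
with rate `rateScaleHz * softplus(drive)` (default scale 20 Hz). The
softplus link is a modelling choice — no quantitative SBP-rate coupling
is established — and the positive baseline keeps the rectifier in its
near-linear regime, preserving the rate–SBP correlation the SBP feature
assumes. One master seed expands into per-stream child seeds so any
single stream regenerates reproducibly.

# Feature extraction choices

* **SBP binning** divides the summed per-ms values by the total raw 2 kHz
  sample count in the bin; trailing partial bins are dropped, never
  zero-padded. Bins are half-open `[start, start + width)` on an integer
  millisecond clock.
* **TCFR** is events per bin divided by bin width (Hz), after coincidence
  artifact removal: any millisecond in which ≥ 20 channels carry an event
  is cleared on all channels (idempotent by construction).
* **The "100 ms Gaussian kernel"** is read as σ = 100 ms (5 bins at
  20 ms), truncated at ±3σ with edge renormalization; a full-width-half-
  maximum reading would give a ~2.4× narrower kernel and is available via
  `interpretation = "fwhm"`.
* **Savitzky–Golay velocities**: positions are averaged into 20 ms bins
  and filtered with a second-order, 7-point (140 ms) filter — the window
  length is not canonical and is exposed — and velocity comes from
  central differences of the smoothed positions. The filter is exact on
  polynomials of degree ≤ 2 and recovers the minimum-jerk peak speed to
  within 2%.
* **EMG envelopes** use a causal second-order Butterworth band-pass
  (100–500 Hz), as online hardware would apply it; a zero-phase option
  exists for offline parity checks. Binned mean absolute value of a
  passband sinusoid of amplitude \(A\) converges to \(2A/\pi\).
* **Peak movement** is the largest local speed maximum after target
  presentation (ties to the earliest bin); 2-DOF speed is the 2-norm over
  both finger groups. A monotone trace returns the global maximum with a
  degenerate-peak flag.

# Tuning and context modulation

For channel \(n\), the standardized 20 ms feature series \(\hat f_n\)
(mean 0, SD 1 over concatenated normal and off-context data) and the
off-context indicator \(c\) form the design \([\hat f_n,\ c \hat f_n]\);
finger position and velocity are regressed on it column-wise at the
channel's optimal lag (the lag within ±10 bins maximizing the L2 norm of
the feature-to-kinematics coefficients, fit on the concatenated data by
default). Inference uses residual-based t statistics with \(T-3\) degrees
of freedom. A channel is *tuned* if either feature coefficient survives
FDR and *context modulated* if either indicator coefficient does.

Two inferential choices deserve comment:

* **FDR families.** By default Benjamini–Hochberg at 0.1% is applied
  separately to the tuning-coefficient family and the modulation-
  coefficient family of a session. Pooling everything into one family
  looks conservative but is not: the tuning p-values are astronomically
  small, so they raise the BH threshold against which the modulation
  coefficients are then judged, inflating false modulation calls several-
  fold on null simulations. Pooling remains available via
  `family = "pooled"`.
* **Calibration limits.** The t-test assumes exchangeable residuals, but
  regression residuals of smooth kinematics on a single channel are
  autocorrelated, which fattens the far tail of the null t distribution.
  With per-family FDR at 0.1% the realized false-modulation rate on null
  generator replicates is ≈ 0.8% — acceptable, but a reminder that the
  bin-level t-test is approximate, exactly as it is in the original
  protocol.

With the indicator identically zero the fit reduces analytically to the
simple regression (the indicator column is dropped); with a single
*off*-context present the design is rank-deficient and the fit refuses.

# Offline decoding

Ridge regression maps 32 ms SBP bins — channels masked to mean TCFR
> 1 Hz, 12 bins of history per channel, lagging never crossing trial
boundaries — to muscle envelopes or to position and velocity of both
finger groups jointly. The intercept is unpenalized; features are
standardized with training-fold statistics only; λ defaults to
generalized cross-validation on the training folds, with a fixed-λ
override for reproducibility. Normal trials are split into 10 folds at
trial boundaries with bin counts as equal as trial granularity allows;
each fold's model is evaluated on its held-out normal bins and on all
off-context bins. Metrics are Pearson r and MSE normalized by the test
set's own variance (nMSE), so the constant-mean predictor scores exactly
1 and nMSE equals one minus the coefficient of determination.

On synthetic sessions the within-context nMSE is far smaller than in
recorded data (≈ 0.003 at the default noise levels) because the synthetic
EMG is nearly a deterministic function of the kinematics; off-context
percent increases are therefore numerically enormous even though the
absolute off-context nMSE (~0.3) is modest. Percent changes on synthetic
sessions measure the generalization *structure*, not the magnitudes a
recording would give.

A decoder trained only on normal trials under-predicts the off-context
flexor envelope by roughly the reciprocal planted gain; the package
estimates this as the ratio of predicted to measured peri-movement
amplitude (flexion-window mean minus extension-window mean, removing the
shared baseline). Recovery is within ~15%: the residual bias comes from
the rectifier's mild asymmetry and from decoder-weight overlap with the
context direction, both of which shrink with channel count.

# Closed-loop simulation

The Kalman decoder is the standard linear-Gaussian position/velocity
filter on the state `[pos_index, pos_mrs, vel_index, vel_mrs, 1]` with a
32 ms update: position rows of the transition matrix are fixed to
physical integration, velocity rows are fit by least squares, the
constant-1 component is preserved exactly, and the online cursor is
updated by integrating the posterior velocity (never by the filter's
position estimate directly), clamped to [0, 100]. This filter structure is
the package's largest inference — the online behavior is specified, the
matrix algebra is standard decoder practice. ReFIT retraining rotates
decoded velocities (magnitudes preserved exactly) onto the cursor-to-
target direction in the raw percent-flexion plane, zeroes them whenever
all fingers are inside their targets, and refits only the observation
matrices.

The intention model that stands in for the subject is a saturated
proportional controller with command noise, an optional re-aim offset
along the target direction ("pushing harder"), a reaction time, and a
160 ms visuomotor feedback delay bridged by a forward model (the subject
extrapolates the seen cursor by its seen velocity). The delay-plus-
forward-model combination is what makes decoder gain mismatches
behaviorally costly: without it the instantaneous feedback simply absorbs
the planted 1.9× flexion gain and acquisition *improves*; with it the
corrupted extrapolation produces overshoot and orbiting, degrading
flexion-target acquisition as the study observed. Trials succeed after
500 ms of continuous hold and fail at a 10 s timeout (the timeout is not
specified anywhere and is configurable). Failed trials are excluded from
between-context performance comparisons but retained for the first-five-
trials adaptation statistic, which z-scores acquisition times within each
context block and tests the early-trial means with Kolmogorov–Smirnov
statistics (the one-sample null is a mean-zero normal with SD
\(1/\sqrt{k}\) for the mean of \(k\) z-scores — approximate, since
within-block z-scoring couples the trials).

# Population geometry

Trials are aligned to their peak-movement bin and a 58-bin window (400 ms
before to 740 ms after, at 20 ms) is cut from smoothed, masked SBP.
Per-context manifolds are the top principal components (16 by default) of
the channel covariance of trial-averaged windows; principal angles
between manifolds are the arccosines of the singular values of the basis
cross-product. The control distribution draws two *disjoint* random sets
of 50 normal trials without replacement, 100 times, and summarizes the
per-rank mean ± SD.

Demixed PCA marginalizes the centered condition averages into
condition-independent (time), context, target, and interaction parts —
an exact additive, mutually orthogonal decomposition whose variance
fractions sum to 1 — and finds per-marginalization encoder/decoder pairs
by ridge-regularized reduced-rank regression (default regularization
1e-6 of total variance). The 16 components are allocated across
marginalizations proportionally to their variance fractions, at least one
each, with an explicit override. Unequal condition counts are balanced by
seeded subsampling to the minimum.

For the comparison of the leading context component with active-muscle
activation, component activation is measured by projecting condition
averages onto the component's unit *encoder pattern*, not by applying the
demixing readout. The demixing decoder reconstructs the target-averaged
context marginalization by construction, so its projection is
target-independent and would erase exactly the per-target structure this
comparison is about; the component's population pattern retains it. With
the default generator the correlations are ≈ +0.97 for flexors (flexion
conditions) and ≈ −0.97 for extensors (extension conditions), opposite
signs reflecting that the same population direction rises when flexion
demands more activation and when extension demands less.

# What the synthetic data do and do not show

The generator emulates: context-dependent muscle gains and
co-contraction; a low-dimensional latent population with a planted,
muscle-referenced context shift orthogonal to movement coding; Poisson
threshold crossings coupled to the SBP drive; the center-out task with
block-interleaved contexts and failure/re-presentation rules. It does not
emulate: electrode noise nonstationarity or unit drift, trial-to-trial
motor variability beyond reaction-time jitter, biomechanical muscle
dynamics, proprioceptive feedback loops, or learning across trials.
Passing tests therefore certify that each implemented operation recovers
what it is supposed to recover under the planted model — not that the
same effect sizes would be observed in recordings. In particular the
dPCA variance fractions, the offline error inflations, and the online
mismatch costs are generator-dependent quantities and are reported, not
targeted.

# Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale,
chosen as the package's own reproducible defaults: sessions of 24–96
channels with context blocks of 25–100 trials for calibration replicates,
one 96-channel six-block (540-trial) session for the end-to-end
quantities, 100-repetition angle controls, and closed-loop runs of
150–240 trials pooled over five simulated arrays. Every random quantity
flows from one seed through named child seeds, so reruns are bit-identical
and any single stream can be regenerated in isolation.
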