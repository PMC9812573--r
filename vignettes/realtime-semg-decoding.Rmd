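---
title: "Decoding wrist and hand kinematics from surface EMG in real time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding wrist and hand kinematics from surface EMG in real time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgdecode)
```

## The decoding problem

A myoelectric prosthesis user produces surface EMG (sEMG) on the forearm;
the controller must turn that multichannel signal into continuous joint
angles — here three degrees of freedom: wrist flexion/extension (DOF1,
flexion positive), pronation/supination (DOF2, pronation positive) and hand
grip (DOF3, nonnegative) — fast enough to feel responsive, and smoothly
enough not to damage motors. `semgdecode` implements that pipeline as
replayable, deterministic code:

1. **Envelope extraction.** Each 120 ms acquisition window (60 samples x 32
   channels at 500 Hz) is rectified and low-pass filtered into an
   integrated-EMG (IEMG) envelope, then min–max normalized per channel
   against a maximum-voluntary-contraction (MVC) calibration recording, so
   every channel lives on a subject- and session-specific `[0, 1]` scale.
2. **Channel-wise convolutional regression.** Six 60-tap temporal filters
   are shared across all 32 channels, compressing each window to a 6 x 32
   "force pattern" map; flattened to 192 features, a fully connected layer
   maps them to the three angles. Two layers, ~2 k parameters — small
   enough to retrain per subject and evaluate in well under a cycle.
3. **Adaptive Kalman smoothing.** One scalar Kalman filter per DOF smooths
   the regressor's output stream; its process and observation covariances
   `Q` and `R` adapt online from the innovation sequence.
4. **Evaluation.** Pearson correlation per DOF and per motion class,
   one-way ANOVA on the per-minute computational-latency groups, and the
   target achievement control (TAC) test with completion-rate curves.

No hardware is needed: a synthetic-data module generates 32-channel sEMG,
MVC recordings and ground-truth angle trajectories with the statistical
structure the pipeline assumes, so every stage is testable end to end.

## The synthetic generator: what it emulates, and what it does not

The generator is a muscle-synergy forward model. Six virtual muscles — an
agonist/antagonist pair per DOF (flexor/extensor, pronator/supinator,
gripper/opener) — are the smallest set that separates all 13 scripted daily
motions (five single, four double-mixture, four triple-mixture; rest is
`M0`). A motion script renders to a plateau-and-ramp angle trajectory;
angles map to activations by a rectified linear scaling that saturates at a
configurable maximum angle (default 30°, the largest TAC target); a
nonnegative 32 x 6 mixing matrix plus a baseline envelope turns activations
into per-channel envelopes; and the raw signal is that envelope multiplying
a zero-mean, unit-variance white Gaussian carrier.

Deliberate simplifications, and their consequences:

* **White carrier.** Real sEMG has a 20–150 Hz band structure; the pipeline
  only consumes the rectified-filtered envelope, so the carrier spectrum is
  irrelevant to the correctness of anything tested here. Tests that pass on
  this generator therefore say nothing about spectral artifacts
  (powerline, motion artifacts) in real recordings.
* **Exactly linear synergy mixing.** Superposition holds bit-exactly in the
  noise-free envelope, which makes parameter-recovery experiments
  well-posed. Real muscle–electrode geometry is only approximately linear.
* **Cosine ramps, default 0.3 s,** between motion plateaus avoid step
  discontinuities in "measured" angles. Scripted plateaus are still a much
  harsher signal than human movement (see the Kalman discussion below).
* **MVC protocol.** The calibration recording holds every virtual muscle at
  full activation, bracketed by 1 s of rest at each end. The rest segments
  are what let the integrated-MVC *minimum* capture the baseline envelope;
  without them the min and max would coincide and the normalization would
  degenerate. A real protocol cues maximal contractions per muscle group;
  the all-muscles-at-once convention is this package's own.

Default study conditions used by the tests and the acceptance script: 10
training trials, each cycling rest + M1–M13 with 1 s holds and 0.5 s rest
(≈ 2.4 synthetic minutes); 5 transfer trials from a perturbed synergy model
(log-normal channel gain jitter, sdlog 0.4, plus a 2-channel sleeve
rotation); windows paired at stride 30 samples. These sizes keep a full
10-fold cross-validation run around a minute and a half on one CPU while
leaving hundreds of windows per held-out trial.

## Signal processing choices

* **FIR taps.** The envelope filter is a linear-phase windowed-sinc
  (Hamming) low-pass, 101 taps, 3 Hz cutoff at 500 Hz, normalized to an
  exactly unit DC gain; coefficients can be replaced wholesale via
  `fir_lowpass(coefficients = ...)` if a different envelope filter is
  preferred. 3 Hz tracks the bandwidth of voluntary wrist movement while
  suppressing the rectified carrier.
* **Streaming state.** `fir_filter()` carries the last `taps - 1` input
  samples per channel between calls, so window-by-window filtering is
  *bit-identical* to filtering the concatenated stream — the real-time loop
  and the offline pipeline can never drift apart. At stream start the state
  is zeros; the first filter length of output is warm-up.
* **MVC profile.** `compute_mvc_profile()` excludes the first two filter
  lengths of output (warm-up plus an equal guard) before taking per-channel
  extrema, so neither the cold-start transient nor leading silence can
  masquerade as the minimum. A flat channel (max ≤ min) is an error naming
  the channel, not a silent degeneracy.
* **Clipping.** Live activation can exceed the calibrated MVC, so
  normalized values are clipped to `[0, 1]`: the regressor was trained on
  that range. Before clipping, normalization is strictly monotone per
  channel.

## The regressor and its training

The forward map is
`force_pattern[j, c] = act(sum_t filter_j[t] * window[t, c] + bias_j)`,
flattened filter-major (filter 1 over channels 1–32 first — fixed so that
serialized weights are portable), then an affine map to degrees. The
post-convolution nonlinearity is ReLU by default with an `"identity"`
switch; the linear case makes the whole network affine and analytically
checkable, and "force patterns" are naturally nonnegative under ReLU.

Training choices (the upstream architecture leaves them open):

* Mean-squared-error loss on the three angles; minibatch Adam (batch 128),
  learning rate `1e-3`, 100 epochs. **Targets are standardized
  internally** by the maximum absolute training angle; the factor is stored
  with the parameters and undone at prediction. Without this, a fixed
  `1e-3` step is dimensionally mismatched to degree-scale outputs and the
  fully connected layer crawls.
* The convolutional filters use He-scaled Gaussian initialization under a
  caller-supplied seed; the fully connected layer starts at zero. All
  randomness (init, minibatch order) derives from the config seed, so a
  fit is exactly reproducible.
* **Cross-validation is grouped by trial**, never by shuffled windows:
  adjacent windows overlap in time, and sample-level splits would leak the
  held-out signal into training. Initial training defaults to 10-fold over
  10 trials; transfer to 5-fold over 5 trials.
* Windows are labelled causally by the up-sampled (120 → 500 Hz, linear
  interpolation) angle at the window's **last** sample, matching real-time
  use where only past EMG exists.

**Layer transfer.** Between sessions the electrode sleeve is re-donned:
per-channel gains change and the sleeve may rotate, but the temporal
structure of an envelope does not. `transfer_cwcnn()` therefore freezes the
convolutional block bit-exactly (the tests compare serialized bytes) and
retrains only the fully connected layer, warm-started, on the new session's
few trials. In the packaged experiments a stale model carried across the
perturbation loses accuracy and transfer restores it; both numbers are
computed, not assumed.

## The adaptive Kalman smoother

Per DOF, with scalars throughout: `K = P/(P + R)`, `x' = x + K (z - x)`,
`P' = (1 - K) P + Q`. The state initializes at the first observation with
`P = R`, avoiding a startup transient toward zero. With adaptation off and
`Q = 0.05`, `R = 0.4` (the defaults), `P` converges to the closed-form
positive root of `P^2 - QP - QR = 0`, `(Q + sqrt(Q^2 + 4QR))/2 ≈ 0.16861`
deg² — an analytic anchor the tests verify to `1e-9`.

Adaptation uses innovation-based moment matching. With innovation
`d = z - x` taken before the update and `P` the covariance before the step:
`R_hat = max(d^2 - P, 1e-4)` and `Q_hat = max(K^2 d^2, 1e-6)`, blended by
the iteration-count running mean `Q(k+1) = Q(k) + (Q_hat - Q(k))/(k + 1)`
(likewise `R`). The running mean makes each covariance exactly the
cumulative average of its estimate sequence — a property the tests assert —
and the floors guarantee positivity for any input, including all-zeros.

**A known limitation, measured rather than hidden:** on the synthetic
scripted sessions the plateau-to-plateau transitions (30° in 0.3 s,
observed at ~8 cycles/s) produce sustained innovations of tens of degrees.
`d^2 - P` then attributes nearly all of that energy to observation noise,
`R` grows large, the gain collapses, and the smoothed stream lags badly:
the smoothed session CC falls well below the raw regressor-output CC that
the acceptance script also reports. This is a real interaction between
running-mean innovation adaptation and fast staircase-like inputs, not an
implementation defect — the same estimators behave reasonably on signals
whose motion is slow relative to the output rate. Whether the adaptive
covariances settle near any particular magnitude depends entirely on the
statistics of the driving signal and is not asserted anywhere.

## The real-time engine

The loop always grabs the **latest** full 60-sample window — samples that
arrive while a cycle is busy are simply never windowed (lossy policy),
trading completeness for freshness as a prosthesis must. Replay is driven
by a simulated clock that advances by the configured cycle period (default
120 ms) per cycle, so results are machine-speed independent and two runs on
the same file are byte-identical. Each grabbed window's filter state is
reconstructed from the source's sample history, which is why the engine's
per-window output equals the offline `process_window()` →
`cwcnn_forward()` → `kf_step()` composition exactly — an invariant the
tests check to the last bit. Computational latency is wall-clock time
around exactly those three stages (never source I/O or output writing), and
a failed cycle is logged and skipped rather than crashing the session.

## Evaluation conventions

* `pearson_cc()` uses sample (N−1) standard deviations, consistent with
  its `1/(N-1)` prefactor; it agrees with the covariance formulation to
  machine precision and refuses constant series.
* Measured angles are aligned to prediction timestamps by linear
  interpolation; motion-class scores concatenate each class's script
  segments, and a class CC is the mean of its per-DOF correlations
  (skipping DOFs the class never recruits).
* Latency stability follows the deliberately strict `p > 0.5` ANOVA
  convention — a no-difference threshold far above the usual 0.05 —
  flagged here because it is unusual.
* TAC: a posture is inside tolerance when **all three DOFs** are
  simultaneously within ±5° (closed interval — the boundary counts, since
  "±5°" does not specify open or closed); the 0.5 s dwell must be
  **continuous** ("stays" implies an unbroken hold, so any exit resets the
  timer); four postures per trial (central → target 1 → target 2 →
  central); 30 s limit. Dwell timing uses the trajectory's own timestamps,
  tolerant of irregular output rates. The completion-rate curve
  `CR(t) = N_completed(t)/4` is right-continuous and nondecreasing.

## Degenerate inputs and numerical edges

* Empty angle series: empty smoothed output, no trace rows.
* Constant MVC channel, non-overlapping stream pairs, underrun at engine
  start, unknown motion ids, missing generator seeds: all loud errors.
* Filtering equivalence is bit-exact by construction (identical arithmetic
  order), so the tests use `identical()`, not tolerances.
* Covariance floors (`1e-6`, `1e-4` deg²) and the `[0, 1]` clip are the
  only saturations in the pipeline; both are documented contracts, not
  hidden clamps.

## What the packaged experiments do and do not show

Passing tests demonstrate that the pipeline is internally consistent
(stream/batch equivalence, engine/offline equivalence, oracle-matched
forward pass and TAC machine), that training recovers a known synthetic
forward model (held-out CC ≥ 0.9 per DOF under grouped cross-validation),
and that frozen-convolution transfer repairs a synergy perturbation. They
do not demonstrate performance on human sEMG: real signals add
nonstationarity, fatigue, crosstalk and electrode-shift effects the
generator deliberately omits, and published human results at comparable
settings (per-DOF CC near 0.8–0.9, ~75 ms computational latency on
laptop-class hardware) should be treated as context, not as quantities this
package reproduces.
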