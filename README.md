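# semgdecode

Real-time decoding of 3-DOF wrist and hand kinematics from 32-channel
surface EMG (sEMG), as a fully replayable R pipeline. It is written for
researchers in myoelectric control who want to study a complete
sEMG-to-joint-angle control loop — envelope extraction, a channel-wise
convolutional regressor, frozen-convolution transfer learning, adaptive
Kalman smoothing, and the standard real-time evaluation protocols — without
any acquisition hardware: a synthetic-data module generates EMG, MVC
calibration recordings and ground-truth angle trajectories with the
statistical structure the pipeline assumes.

## The model

Raw sEMG windows (60 samples × 32 channels: 120 ms at 500 Hz) become
normalized integrated EMG (IEMG) per channel *i*:

    IEMG_i      = filter(|EMG_i|)                     (rectify + low-pass FIR)
    IEMG_norm_i = (IEMG_i − min IMVC_i) / (max IMVC_i − min IMVC_i)

where IMVC is the MVC calibration recording processed identically. A
channel-wise CNN then maps each window to the three joint angles: six
60-tap temporal filters, shared across channels, produce a 6 × 32 "force
pattern" map

    F[j, c] = act( Σ_t w_j[t] · window[t, c] + b_j ),

flattened to 192 features and mapped affinely to (DOF1, DOF2, DOF3) in
degrees — wrist flexion/extension, pronation/supination, grip. Across
sessions only the fully connected layer is retrained ("layer transfer");
the convolutional block is frozen bit-exactly. Each DOF's output stream is
smoothed by a scalar adaptive Kalman filter

    K = P/(P+R),  x ← x + K(z − x),  P ← (1−K)P + Q,

with Q and R updated after every iteration as iteration-count running means
of innovation-based variance estimates. Accuracy is scored with the Pearson
correlation coefficient (CC) per DOF and per motion class, latency
stability with one-way ANOVA over per-minute groups (stability declared at
p > 0.5), and closed-loop usability with the target achievement control
(TAC) test: ±5° tolerance on all three DOFs simultaneously, 0.5 s
continuous dwell, 30 s trial limit, completion rate CR(t) = N_completed(t)/4.

## Worked example

Simulate four trials of the 13 daily motions, calibrate on the session's
MVC recording, train with trial-grouped cross-validation, then replay the
raw EMG through the real-time engine:

```r
library(semgdecode)

model   <- synergy_model()
scripts <- replicate(4, trial_script(), simplify = FALSE)
session <- simulate_session(scripts, model, seed = 1)

profile <- compute_mvc_profile(session$mvc)
iemg    <- process_stream(session$emg, profile)
iemg$trial <- session$emg$trial

pairs <- pair_windows(iemg, session$angles)
pairs
#> <training_pairs> 928 pairs (60 x 32 windows, 3 DOFs, 4 trials)

fit <- train_cwcnn(pairs, folds = 4, epochs = 100, seed = 2)
fit
#> <cwcnn_fit> initial, 4-fold CV mean held-out CC: dof1=0.970 dof2=0.972 dof3=0.987
```

Held-out CC near 1 per DOF means the regressor recovers the known synthetic
angle→EMG forward model almost perfectly on trials it never saw. Replaying
the session through the engine exercises the latest-window lossy policy,
the streaming filter state and the adaptive smoother, and scores the
smoothed output against the ground-truth angles:

```r
out <- run_session(fit, session$emg, profile)
score_session(out$angles, session$angles, scripts)
#> # A tibble: 7 × 4
#>   scope level     cc     n
#> 1 dof   dof1   0.409   466
#> 2 dof   dof2   0.530   466
#> 3 dof   dof3   0.434   466
#> 4 class single 0.249   166
#> 5 class double 0.309   134
#> 6 class triple 0.355   133
#> 7 class all    0.496   433

round(mean(out$latency$duration_ms), 2)
#> [1] 2.52
```

The drop from the cross-validated CC is the adaptive Kalman stage: on
scripted plateau-to-plateau motions the innovation-based R estimate grows
large and the smoother lags (the raw per-cycle outputs in
`out$angles$raw_dof*` score ≈ 0.97; see the methods vignette for the
analysis). The latency number is the wall-clock cost of the three decode
stages per 120 ms cycle.

A scripted reference trajectory completes a TAC trial:

```r
cfg <- tac_config("TAC-1")
res <- tac_evaluate(tac_reference_trajectory(cfg, hold = 0.6), cfg)
res
#> <tac_result> TAC-1: 4/4 postures, trial time 3.72 s
completion_rate_curve(res)
#> # A tibble: 6 × 2
#>    time    cr
#> 1  0     0
#> 2  0.5   0.25
#> 3  1.44  0.5
#> 4  2.54  0.75
#> 5  3.72  1
#> 6 30     1
```

Each 0.25 step is one posture (central → target 1 → target 2 → central)
completing after its continuous 0.5 s dwell.

`autoplot()` methods exist for fits and TAC results, plus
`plot_kalman_trace()` for Q/R convergence and `plot_completion_rate()` for
CR curves; `tidy()`/`glance()` give broom-style summaries of fits.

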