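test_that("rendered trajectories follow the motion catalogue", {
  # rest is the zero posture, sampled right-open at the nominal rate
  rest <- render_angle_trajectory(motion_script("M0", 1), rate = 120)
  expect_equal(nrow(rest), 120)
  expect_true(all(as.matrix(rest[, c("dof1", "dof2", "dof3")]) == 0))

  # wrist flexion drives DOF1 positive only
  wf <- render_angle_trajectory(motion_script("M1", 1), rate = 120)
  plateau <- wf[wf$time > 0.5, ]
  expect_true(all(plateau$dof1 > 0))
  expect_true(all(plateau$dof2 == 0) && all(plateau$dof3 == 0))
  expect_equal(max(wf$dof1), 30)

  # deterministic: identical inputs give identical outputs
  s <- motion_script(c("M0", "M5", "M0"), c(0.5, 1, 0.5))
  expect_identical(render_angle_trajectory(s), render_angle_trajectory(s))

  # grip never goes negative across every motion; rest entries must be
  # longer than the 0.3 s transition ramp for the posture to settle
  all_m <- render_angle_trajectory(trial_script(hold = 0.5, rest = 0.4))
  expect_true(all(all_m$dof3 >= 0))

  # scripts bracketed by rest start and end at the boundary posture
  expect_equal(unlist(all_m[1, c("dof1", "dof2", "dof3")]),
               c(dof1 = 0, dof2 = 0, dof3 = 0))
  expect_equal(unlist(all_m[nrow(all_m), c("dof1", "dof2", "dof3")]),
               c(dof1 = 0, dof2 = 0, dof3 = 0))
})

test_that("invalid scripts are rejected", {
  expect_error(motion_script("M99", 1), "Unknown motion")
  expect_error(motion_script("M1", -1), "> 0")
})

test_that("angle-to-activation map is a rectified linear scaling", {
  zeros <- tibble::tibble(time = 0:2, dof1 = 0, dof2 = 0, dof3 = 0)
  act0 <- angles_to_activations(zeros)
  expect_true(all(as.matrix(act0[, -1]) == 0))

  ang <- tibble::tibble(time = 0:3,
                        dof1 = c(30, -15, 0, 60),
                        dof2 = c(0, -15, 15, 0),
                        dof3 = c(0, 0, 30, 15))
  act <- angles_to_activations(ang, max_angle = 30)
  expect_equal(act$flex, c(1, 0, 0, 1)) # saturates at max_angle
  expect_equal(act$ext, c(0, 0.5, 0, 0))
  expect_equal(act$sup, c(0, 0.5, 0, 0)) # -max/2 -> antagonist at 0.5
  expect_equal(act$pron, c(0, 0, 0.5, 0))
  expect_equal(act$grip, c(0, 0, 1, 0.5))
  expect_true(all(as.matrix(act[, -1]) >= 0 & as.matrix(act[, -1]) <= 1))
})

test_that("synthetic EMG is seeded, amplitude-modulated, zero-mean noise", {
  model <- synergy_model()
  act <- tibble::tibble(time = seq(0, 30, by = 1 / 120),
                        flex = 0, ext = 0, pron = 0, sup = 0,
                        grip = 0, open = 0)
  expect_error(synthesize_emg(act, model), "seed")

  emg1 <- synthesize_emg(act, model, seed = 11)
  emg2 <- synthesize_emg(act, model, seed = 11)
  expect_identical(emg1, emg2)
  expect_false(identical(emg1, synthesize_emg(act, model, seed = 12)))

  # at rest the per-channel sd is the baseline envelope (>= 1e4 samples)
  mat <- as.matrix(emg1[, emg_channel_names()])
  expect_gte(nrow(mat), 1e4)
  sds <- apply(mat, 2, sd)
  expect_true(all(abs(sds - model$baseline_noise) / model$baseline_noise
                  < 0.05))
  expect_lt(max(abs(colMeans(mat))), 0.01)
})

test_that("the noise-free envelope is exactly linear in activations", {
  model <- synergy_model()
  base <- tibble::tibble(time = 0:4, flex = runif(5), ext = runif(5),
                         pron = runif(5), sup = runif(5), grip = runif(5),
                         open = runif(5))
  doubled <- base
  doubled$grip <- 2 * base$grip
  e_base <- activation_envelope(base, model)
  e_doubled <- activation_envelope(doubled, model)
  contrib <- outer(base$grip, model$mixing[, "grip"])
  # doubling one activation column adds exactly one more unit of its
  # mixing contribution (superposition, to summation rounding)
  expect_equal(e_doubled - e_base, contrib, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("MVC recordings hit the full-activation envelope", {
  model <- synergy_model()
  mvc <- synthesize_mvc(model, duration = 6, seed = 5)
  expect_identical(mvc, synthesize_mvc(model, duration = 6, seed = 5))
  expect_equal(length(emg_columns_test(mvc)), 32)
  expect_equal(round(1 / median(diff(mvc$time))), 500)

  # during the burst, per-channel envelope = row sum of mixing + baseline;
  # the sd of the modulated carrier estimates it
  burst <- mvc[mvc$time > 1.5 & mvc$time < 4.5, ]
  sds <- apply(as.matrix(burst[, emg_columns_test(mvc)]), 2, sd)
  expected <- rowSums(model$mixing) + model$baseline_noise
  expect_true(all(abs(sds - expected) / expected < 0.1))
})

test_that("synergy model construction is validated and reproducible", {
  m <- synergy_model()
  expect_true(all(m$mixing >= 0))
  expect_true(all(colSums(m$mixing) > 0))
  expect_error(synergy_model(gain_jitter = 0.5), "seed")
  j1 <- synergy_model(gain_jitter = 0.5, seed = 3)
  expect_identical(j1, synergy_model(gain_jitter = 0.5, seed = 3))
  expect_true(all(j1$mixing >= 0))
})
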