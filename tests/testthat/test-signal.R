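test_that("rectification is the idempotent absolute value", {
  expect_equal(rectify(-1.5), 1.5)
  expect_equal(rectify(0), 0)
  x <- matrix(rnorm(200), 20)
  expect_identical(rectify(rectify(x)), rectify(x))
})

test_that("the default envelope filter is a unit-DC-gain low-pass FIR", {
  spec <- fir_lowpass()
  expect_length(spec$coefficients, 101)
  expect_equal(spec$dc_gain, 1, tolerance = 1e-12)

  # steady state of a constant equals the constant (DC gain)
  const <- matrix(2.5, 500, 3)
  y <- fir_filter(const, spec)$values
  expect_equal(unname(y[500, ]), rep(2.5, 3), tolerance = 1e-12)

  # impulse response reproduces the tap sequence
  imp <- matrix(0, 150, 1)
  imp[1, 1] <- 1
  y <- fir_filter(imp, spec)$values
  expect_equal(y[1:101, 1], spec$coefficients, tolerance = 1e-15)
})

test_that("windowed filtering with carried state is bit-exact", {
  spec <- fir_lowpass()
  set.seed(42)
  x <- matrix(rnorm(3200), ncol = 4)
  oneshot <- fir_filter(x, spec)$values

  # random window split
  cuts <- sort(sample(2:(nrow(x) - 1), 10))
  bounds <- cbind(c(1, cuts), c(cuts - 1, nrow(x)))
  state <- NULL
  pieces <- list()
  for (i in seq_len(nrow(bounds))) {
    res <- fir_filter(x[bounds[i, 1]:bounds[i, 2], , drop = FALSE], spec,
                      state = state)
    state <- res$state
    pieces[[i]] <- res$values
  }
  expect_identical(do.call(rbind, pieces), unname(oneshot))

  # mismatched state shape is an error
  expect_error(fir_filter(x, spec, state = matrix(0, 5, 4)), "state")
})

test_that("MVC profiles capture baseline minima and burst maxima", {
  model <- synergy_model()
  mvc <- synthesize_mvc(model, duration = 6, seed = 5)
  prof <- compute_mvc_profile(mvc)
  expect_equal(nrow(prof), 32)
  expect_true(all(prof$max > prof$min))

  # rectified N(0, env) has mean env * sqrt(2/pi): the settled filtered
  # burst tracks the analytic full-activation envelope closely, while the
  # profile extremes bracket it (max sits a few filtered-noise sd above,
  # min a few below the rest envelope)
  env_full <- (rowSums(model$mixing) + model$baseline_noise) * sqrt(2 / pi)
  filt <- fir_filter(rectify(as.matrix(mvc[, emg_columns_test(mvc)])),
                     fir_lowpass())$values
  burst <- filt[mvc$time > 1.5 & mvc$time < 4.5, ]
  expect_true(all(abs(colMeans(burst) - env_full) / env_full < 0.05))
  expect_true(all(prof$max > env_full & prof$max < 1.4 * env_full))
  env_rest <- model$baseline_noise * sqrt(2 / pi)
  expect_true(all(prof$min < 1.02 * env_rest & prof$min > 0.6 * env_rest))

  # prepending a filter length of zeros leaves the profile essentially
  # unchanged: the burst maximum exactly (same settled outputs), the rest
  # minimum within the rest envelope's sampling fluctuation (the settled
  # region gains a short stretch of extra rest samples)
  nb <- length(fir_lowpass()$coefficients)
  pad <- mvc[seq_len(nb - 1), ]
  pad[emg_columns_test(mvc)] <- 0
  pad$time <- pad$time - max(pad$time) - 1 / 500
  padded <- dplyr::bind_rows(pad, mvc)
  prof_pad <- compute_mvc_profile(padded)
  expect_equal(prof_pad$max, prof$max, tolerance = 1e-12)
  expect_equal(prof_pad$min, prof$min, tolerance = 0.1)

  # a flat channel cannot be normalized against
  flat <- mvc
  flat$ch07 <- 1
  expect_error(compute_mvc_profile(flat), "ch07")
})

test_that("normalization matches the min-max formula and clips to [0, 1]", {
  prof <- tibble::tibble(channel = "ch01", min = 0.1, max = 0.6)
  class(prof) <- c("mvc_profile", class(prof))
  expect_equal(normalize_iemg(matrix(0.35), prof)[1, 1], 0.5)
  expect_equal(normalize_iemg(matrix(0.1), prof)[1, 1], 0)
  expect_equal(normalize_iemg(matrix(0.6), prof)[1, 1], 1)
  # out-of-range values clip
  expect_equal(normalize_iemg(matrix(2), prof)[1, 1], 1)
  expect_equal(normalize_iemg(matrix(-1), prof)[1, 1], 0)

  # monotone in the raw envelope before clipping
  vals <- seq(0.1, 0.6, length.out = 20)
  out <- normalize_iemg(matrix(vals, ncol = 1), prof)
  expect_true(all(diff(out[, 1]) > 0))
})

test_that("process_window equals the explicit three-step composition", {
  model <- synergy_model()
  ses <- small_session(trials = 1, hold = 0.4, rest = 0.2)
  prof <- compute_mvc_profile(ses$mvc)
  spec <- fir_lowpass()

  raw <- as.matrix(ses$emg[1:60, emg_columns_test(ses$emg)])
  res <- process_window(raw, prof, spec)
  expect_equal(dim(res$values), c(60, 32))
  expect_true(all(res$values >= 0 & res$values <= 1))

  manual <- normalize_iemg(fir_filter(rectify(raw), spec)$values, prof)
  expect_identical(res$values, manual)

  # all-zero raw window against a zero-minimum profile stays zero
  prof0 <- prof
  prof0$min <- 0
  zero <- process_window(matrix(0, 60, 32), prof0, spec)
  expect_true(all(zero$values == 0))
})

test_that("whole-stream processing stays in [0, 1] and matches windowing", {
  ses <- small_session(trials = 1, hold = 0.4, rest = 0.2)
  spec <- fir_lowpass()
  prof <- compute_mvc_profile(ses$mvc, spec)
  norm <- process_stream(ses$emg, prof, spec)
  mat <- as.matrix(norm[, emg_columns_test(norm)])
  expect_true(all(mat >= 0 & mat <= 1))

  # window-by-window processing with carried state reproduces the stream
  raw <- as.matrix(ses$emg[, emg_columns_test(ses$emg)])
  state <- NULL
  out <- matrix(NA_real_, nrow(raw), ncol(raw))
  for (s in seq(1, nrow(raw) - 59, by = 60)) {
    res <- process_window(raw[s:(s + 59), ], prof, spec, state = state)
    state <- res$state
    out[s:(s + 59), ] <- res$values
  }
  done <- !is.na(out[, 1])
  expect_identical(out[done, ], unname(mat[done, ]))
})
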