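test_that("forward pass matches its structural contract", {
  p <- cwcnn_init(seed = 2)
  expect_equal(dim(p$conv_w), c(6, 60))
  expect_equal(dim(p$fc_w), c(3, 192)) # 6 filters x 32 channels

  # zero fc weights: output is the fc bias regardless of the window
  p0 <- p
  p0$fc_b <- c(1, -2, 3)
  w <- matrix(runif(60 * 32), 60)
  expect_equal(unname(cwcnn_forward(p0, w)), c(1, -2, 3))
  expect_equal(unname(cwcnn_forward(p0, w * 0)), c(1, -2, 3))

  expect_error(cwcnn_forward(p, matrix(0, 59, 32)), "60 rows")
})

test_that("forward pass equals the brute-force double-loop oracle", {
  set.seed(31)
  for (i in 1:100) {
    act <- if (i %% 2 == 0) "relu" else "identity"
    p <- cwcnn_init(activation = act, seed = i)
    p$conv_b <- rnorm(6)
    p$fc_w <- matrix(rnorm(3 * 192), 3)
    p$fc_b <- rnorm(3)
    p$y_scale <- runif(1, 0.5, 40)
    w <- matrix(rnorm(60 * 32), 60)
    got <- unname(cwcnn_forward(p, w))
    want <- brute_force_forward(p, w)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("output is linear in the fully connected parameters", {
  p <- cwcnn_init(seed = 4)
  w <- matrix(runif(60 * 32), 60)
  pa <- p; pa$fc_w <- matrix(rnorm(3 * 192), 3); pa$fc_b <- rnorm(3)
  pb <- p; pb$fc_w <- matrix(rnorm(3 * 192), 3); pb$fc_b <- rnorm(3)
  psum <- p
  psum$fc_w <- pa$fc_w + pb$fc_w
  psum$fc_b <- pa$fc_b + pb$fc_b
  expect_equal(cwcnn_forward(psum, w),
               cwcnn_forward(pa, w) + cwcnn_forward(pb, w),
               tolerance = 1e-12)
})

test_that("pairing aligns windows with up-sampled angle labels", {
  # constant angles label every pair with that constant
  n <- 500
  iemg <- tibble::tibble(time = (0:(n - 1)) / 500)
  for (cn in emg_channel_names(4)) iemg[[cn]] <- runif(n)
  angles <- tibble::tibble(time = seq(0, 1, by = 1 / 120),
                           dof1 = 10, dof2 = 10, dof3 = 10)
  pairs <- pair_windows(iemg, angles, window_len = 60, stride = 30)
  expect_true(all(pairs$Y == 10))

  # pair count follows floor((M - 60) / stride) + 1
  expect_equal(pairs$n, floor((n - 60) / 30) + 1)
  p2 <- pair_windows(iemg, angles, window_len = 60, stride = 7)
  expect_equal(p2$n, floor((n - 60) / 7) + 1)

  # labels interpolate linearly at the window's last sample
  ramp <- tibble::tibble(time = c(0, 1), dof1 = c(0, 100),
                         dof2 = c(0, 0), dof3 = c(0, 0))
  p3 <- pair_windows(iemg, ramp, window_len = 60, stride = 30)
  expect_equal(p3$Y[1, ], 100 * p3$t_end, tolerance = 1e-9)

  # non-overlapping streams fail loudly
  late <- angles
  late$time <- late$time + 100
  expect_error(pair_windows(iemg, late, 60, 30), "overlap")
})

test_that("training is seeded, reports folds, and rejects bad input", {
  # tiny linear toy problem: envelope of 4 channels -> angles
  set.seed(9)
  n <- 600
  iemg <- tibble::tibble(time = (0:(n - 1)) / 500,
                         trial = rep(1:3, each = n / 3))
  drive <- rep(runif(n / 50), each = 50)
  for (cn in emg_channel_names(4)) iemg[[cn]] <- drive + rnorm(n, sd = 0.01)
  angles <- tibble::tibble(time = iemg$time, dof1 = 20 * drive,
                           dof2 = -20 * drive, dof3 = 10 * drive)
  pairs <- pair_windows(iemg, angles, window_len = 20, stride = 10)

  fit1 <- train_cwcnn(pairs, folds = 3, epochs = 10, seed = 5)
  fit2 <- train_cwcnn(pairs, folds = 3, epochs = 10, seed = 5)
  expect_identical(fit1$loss, fit2$loss)
  expect_identical(fit1$params, fit2$params)

  expect_equal(sort(unique(fit1$cv$fold)), 1:3)
  expect_equal(nrow(fit1$cv), 3 * 3) # folds x DOFs
  expect_identical(tidy(fit1), fit1$cv)
  expect_equal(glance(fit1)$folds, 3)

  expect_error(train_cwcnn(pairs, folds = 5, epochs = 1), "5")
})

test_that("layer transfer freezes the convolutional block bit-exactly", {
  set.seed(10)
  n <- 600
  iemg <- tibble::tibble(time = (0:(n - 1)) / 500,
                         trial = rep(1:5, each = n / 5))
  drive <- rep(runif(n / 50), each = 50)
  for (cn in emg_channel_names(4)) iemg[[cn]] <- drive + rnorm(n, sd = 0.01)
  angles <- tibble::tibble(time = iemg$time, dof1 = 20 * drive,
                           dof2 = -20 * drive, dof3 = 10 * drive)
  pairs <- pair_windows(iemg, angles, window_len = 20, stride = 10)

  fit <- train_cwcnn(pairs, folds = 2, epochs = 8, seed = 5)
  upd <- transfer_cwcnn(fit, pairs, folds = 5, epochs = 8, seed = 6)

  # freezing contract: conv weights and biases identical to the last bit
  expect_identical(upd$params$conv_w, fit$params$conv_w)
  expect_identical(upd$params$conv_b, fit$params$conv_b)
  expect_identical(serialize(upd$params$conv_w, NULL),
                   serialize(fit$params$conv_w, NULL))
  # the fully connected layer did move
  expect_false(identical(upd$params$fc_w, fit$params$fc_w))
  # default transfer CV is 5-fold
  expect_equal(max(upd$cv$fold), 5)
  expect_equal(upd$config$mode, "transfer")
})

test_that("model containers round-trip bit-exactly through JSON", {
  p <- cwcnn_init(seed = 3)
  p$conv_b <- rnorm(6)
  p$fc_w <- matrix(rnorm(3 * 192), 3)
  p$fc_b <- rnorm(3)
  p$y_scale <- 31.4159
  path <- withr::local_tempfile(fileext = ".json")
  write_cwcnn(p, path)
  back <- read_cwcnn(path)
  expect_identical(back$params$conv_w, p$conv_w)
  expect_identical(back$params$fc_w, p$fc_w)
  expect_identical(back$params$fc_b, p$fc_b)
  expect_identical(back$params$y_scale, p$y_scale)
  expect_identical(back$params$activation, p$activation)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), bad)
  expect_error(read_cwcnn(bad), "container")
})
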