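#' Initialize channel-wise CNN parameters
#'
#' The regressor has two layers. A convolutional layer holds six temporal
#' filters of 60 taps each (one bias per filter); every filter is applied to
#' every channel of the 60 x 32 normalized-IEMG window, compressing the time
#' dimension to a 6 x 32 "force pattern" map. The map is flattened
#' filter-major into a 192-vector, and a fully connected layer maps it to
#' the 3 joint angles. Filters use He-scaled Gaussian init; the fully
#' connected layer starts at zero so the initial output is the bias alone.
#'
#' @param n_filters Number of temporal filters (default 6).
#' @param window_len Samples per window (default 60).
#' @param n_channels Electrode channels (default 32).
#' @param n_out Output DOFs (default 3).
#' @param activation Post-convolution nonlinearity: `"relu"` (default) or
#'   `"identity"` (makes the network affine, useful for analytic checks).
#' @param seed Integer seed for the filter init.
#' @return Object of class `cwcnn_params`: list with `conv_w`
#'   (n_filters x window_len), `conv_b` (n_filters), `fc_w`
#'   (n_out x n_filters*n_channels), `fc_b` (n_out), `activation`, and
#'   `y_scale` (target standardization factor, degrees; 1 until trained).
#' @export
cwcnn_init <- function(n_filters = 6, window_len = 60, n_channels = 32,
                       n_out = 3, activation = c("relu", "identity"),
                       seed = 1) {
  activation <- match.arg(activation)
  conv_w <- withr_seed(seed, matrix(
    rnorm(n_filters * window_len, sd = sqrt(2 / window_len)),
    nrow = n_filters
  ))
  structure(
    list(
      conv_w = conv_w,
      conv_b = numeric(n_filters),
      fc_w = matrix(0, nrow = n_out, ncol = n_filters * n_channels),
      fc_b = numeric(n_out),
      activation = activation,
      y_scale = 1
    ),
    class = "cwcnn_params"
  )
}

act_fun <- function(z, tag) if (tag == "relu") pmax(z, 0) else z

#' CW-CNN forward pass
#'
#' `force_pattern[j, c] = act(sum_t filter_j[t] * window[t, c] + bias_j)`;
#' the 6 x 32 map is flattened row-major (filter-major) to 192 features and
#' mapped affinely to the 3 output angles (degrees).
#'
#' @param params A `cwcnn_params` object.
#' @param window Numeric matrix, window_len x n_channels (60 x 32).
#' @return Named numeric 3-vector `c(dof1, dof2, dof3)` in degrees.
#' @export
cwcnn_forward <- function(params, window) {
  window <- as.matrix(window)
  if (nrow(window) != ncol(params$conv_w)) {
    abort(sprintf("Window must have %d rows, got %d.",
                  ncol(params$conv_w), nrow(window)))
  }
  fp <- act_fun(params$conv_w %*% window + params$conv_b, params$activation)
  feats <- as.numeric(t(fp)) # filter-major: filter 1 over all channels first
  if (length(feats) != ncol(params$fc_w)) {
    abort("Channel count incompatible with fully connected layer.")
  }
  out <- as.numeric(params$fc_w %*% feats + params$fc_b) * params$y_scale
  names(out) <- c("dof1", "dof2", "dof3")[seq_along(out)]
  out
}

# Batched forward. X: window_len x (n_channels * N) with windows side by side.
# Returns list(feats = F x N feature matrix (F = n_filters*n_channels),
#              pre = preactivation conv map, y = n_out x N)
cwcnn_forward_batch <- function(params, X, n_channels) {
  pre <- params$conv_w %*% X + params$conv_b # n_filters x (n_channels*N)
  fp <- act_fun(pre, params$activation)
  nf <- nrow(params$conv_w)
  N <- ncol(X) / n_channels
  # rearrange to (nf*n_channels) x N, filter-major within a window
  feats <- matrix(aperm(array(fp, c(nf, n_channels, N)), c(2, 1, 3)),
                  nrow = nf * n_channels)
  y <- params$fc_w %*% feats + params$fc_b
  list(pre = pre, feats = feats, y = y)
}

#' Pair EMG windows with time-aligned joint-angle targets
#'
#' Builds supervised training pairs: angles recorded at the motion-capture
#' rate (120 Hz) are up-sampled by linear interpolation onto the EMG
#' timestamps (500 Hz); each pair is one `window_len`-sample normalized-IEMG
#' window labelled with the up-sampled angle at the window's *last* sample
#' (causal labelling, matching real-time use). Windows never straddle trial
#' boundaries when a `trial` column is present.
#'
#' @param iemg Normalized IEMG tibble (`time` + channel columns, optional
#'   `trial`), e.g. from [process_stream()].
#' @param angles Angle tibble (`time`, `dof1..3`) at any rate covering the
#'   EMG time span.
#' @param window_len Samples per window (default 60).
#' @param stride Hop between consecutive windows in samples (default 30).
#' @return Object of class `training_pairs`: list with `X` (window_len x
#'   (n_channels * N) matrix, windows side by side), `Y` (n_out x N),
#'   `t_end`, `trial`, `n_channels`, `n`.
#' @export
pair_windows <- function(iemg, angles, window_len = 60, stride = 30) {
  ch <- emg_columns(iemg)
  if (max(angles$time) < min(iemg$time) || min(angles$time) > max(iemg$time)) {
    abort("EMG and angle streams do not overlap in time.")
  }
  trial <- if ("trial" %in% names(iemg)) iemg$trial else rep(1L, nrow(iemg))
  dofs <- intersect(c("dof1", "dof2", "dof3"), names(angles))
  ang_up <- vapply(
    dofs,
    function(d) approx(angles$time, angles[[d]], xout = iemg$time, rule = 2)$y,
    numeric(nrow(iemg))
  )
  mat <- as.matrix(iemg[, ch])
  Xs <- list(); Ys <- list(); te <- list(); tr <- list()
  for (g in unique(trial)) {
    idx <- which(trial == g)
    M <- length(idx)
    if (M < window_len) next
    ends <- seq(window_len, M, by = stride)
    Xg <- matrix(0, window_len, length(ch) * length(ends))
    for (k in seq_along(ends)) {
      rows <- idx[(ends[k] - window_len + 1):ends[k]]
      Xg[, ((k - 1) * length(ch) + 1):(k * length(ch))] <- mat[rows, ]
    }
    Xs[[length(Xs) + 1]] <- Xg
    Ys[[length(Ys) + 1]] <- t(ang_up[idx[ends], , drop = FALSE])
    te[[length(te) + 1]] <- iemg$time[idx[ends]]
    tr[[length(tr) + 1]] <- rep(g, length(ends))
  }
  if (length(Xs) == 0) abort("No trial holds a full window of samples.")
  structure(
    list(
      X = do.call(cbind, Xs), Y = do.call(cbind, Ys),
      t_end = unlist(te), trial = unlist(tr),
      n_channels = length(ch), n = length(unlist(te))
    ),
    class = "training_pairs"
  )
}

#' @export
print.training_pairs <- function(x, ...) {
  cat(sprintf(
    "<training_pairs> %d pairs (%d x %d windows, %d DOFs, %d trials)\n",
    x$n, nrow(x$X), x$n_channels, nrow(x$Y), length(unique(x$trial))
  ))
  invisible(x)
}

subset_pairs <- function(pairs, keep) {
  nc <- pairs$n_channels
  cols <- as.vector(outer(seq_len(nc), (keep - 1) * nc, "+"))
  structure(
    list(
      X = pairs$X[, cols, drop = FALSE],
      Y = pairs$Y[, keep, drop = FALSE],
      t_end = pairs$t_end[keep], trial = pairs$trial[keep],
      n_channels = nc, n = length(keep)
    ),
    class = "training_pairs"
  )
}

adam_new <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, s), v = array(0, s), t = 0))
}

adam_step <- function(st, g, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mhat <- st$m / (1 - b1^st$t)
  vhat <- st$v / (1 - b2^st$t)
  st$delta <- lr * mhat / (sqrt(vhat) + eps)
  st
}

# One optimization run over pairs. Returns updated params and final loss.
# freeze_conv: skip conv gradient updates entirely (layer transfer).
cwcnn_optimize <- function(params, pairs, epochs, lr, batch_size, seed,
                           freeze_conv = FALSE) {
  nc <- pairs$n_channels
  nf <- nrow(params$conv_w)
  Ys <- pairs$Y / params$y_scale
  opt <- adam_new(list(
    conv_w = dim(params$conv_w), conv_b = length(params$conv_b),
    fc_w = dim(params$fc_w), fc_b = length(params$fc_b)
  ))
  order_seed <- seed
  loss <- NA_real_
  for (ep in seq_len(epochs)) {
    perm <- withr_seed(order_seed + ep, sample.int(pairs$n))
    starts <- seq(1, pairs$n, by = batch_size)
    for (s in starts) {
      keep <- perm[s:min(s + batch_size - 1, pairs$n)]
      nb <- length(keep)
      cols <- as.vector(outer(seq_len(nc), (keep - 1) * nc, "+"))
      Xb <- pairs$X[, cols, drop = FALSE]
      Yb <- Ys[, keep, drop = FALSE]
      fwd <- cwcnn_forward_batch(params, Xb, nc)
      err <- fwd$y - Yb # n_out x nb
      loss <- mean(err^2)
      if (!is.finite(loss)) abort("Training diverged: non-finite loss.")
      dY <- 2 * err / (nb * nrow(err))
      g_fc_w <- dY %*% t(fwd$feats)
      g_fc_b <- rowSums(dY)
      params$fc_w <- params$fc_w - {
        opt$fc_w <- adam_step(opt$fc_w, g_fc_w, lr); opt$fc_w$delta
      }
      params$fc_b <- as.numeric(params$fc_b - {
        opt$fc_b <- adam_step(opt$fc_b, g_fc_b, lr); opt$fc_b$delta
      })
      if (!freeze_conv) {
        dFeat <- t(params$fc_w) %*% dY # (nf*nc) x nb
        dfp <- matrix(
          aperm(array(dFeat, c(nc, nf, nb)), c(2, 1, 3)),
          nrow = nf
        ) # nf x (nc*nb), matches fwd$pre layout
        if (params$activation == "relu") dfp <- dfp * (fwd$pre > 0)
        g_conv_w <- dfp %*% t(Xb)
        g_conv_b <- rowSums(dfp)
        params$conv_w <- params$conv_w - {
          opt$conv_w <- adam_step(opt$conv_w, g_conv_w, lr); opt$conv_w$delta
        }
        params$conv_b <- as.numeric(params$conv_b - {
          opt$conv_b <- adam_step(opt$conv_b, g_conv_b, lr); opt$conv_b$delta
        })
      }
    }
  }
  list(params = params, loss = loss)
}

fold_assignment <- function(trial, folds) {
  u <- sort(unique(trial))
  if (length(u) < folds) {
    abort(sprintf("Need at least %d trials for %d-fold grouped CV.",
                  folds, folds))
  }
  trial_fold <- rep(seq_len(folds), length.out = length(u))
  trial_fold[match(trial, u)]
}

#' Train the CW-CNN with grouped k-fold cross-validation
#'
#' Splits trials (not samples) into `folds` groups to avoid temporal
#' leakage, trains one network per fold on the remaining trials, scores the
#' held-out fold with the per-DOF Pearson correlation, then trains the
#' final network on all pairs. Targets are standardized internally by
#' `max(abs(Y))` so the optimizer's step size is scale-free; the factor is
#' stored in the returned parameters and undone at prediction time.
#'
#' @param pairs A [pair_windows()] result.
#' @param folds Number of CV folds (default 10).
#' @param epochs Passes over the training data per fit (default 100).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 128).
#' @param activation Post-conv nonlinearity, see [cwcnn_init()].
#' @param seed Integer seed controlling init and minibatch order.
#' @return Object of class `cwcnn_fit`: list with `params`
#'   (`cwcnn_params`), `cv` (tibble fold x dof with held-out `cc`),
#'   `config`, `loss` (final training loss, standardized units).
#' @export
train_cwcnn <- function(pairs, folds = 10, epochs = 100, lr = 1e-3,
                        batch_size = 128, activation = "relu", seed = 1) {
  stopifnot(folds >= 2, epochs >= 1)
  if (pairs$n < folds * 2) abort("Too few pairs for the requested folds.")
  y_scale <- max(abs(pairs$Y))
  if (y_scale == 0) y_scale <- 1
  init <- function() {
    p <- cwcnn_init(
      window_len = nrow(pairs$X), n_channels = pairs$n_channels,
      n_out = nrow(pairs$Y), activation = activation, seed = seed
    )
    p$y_scale <- y_scale
    p
  }
  assign_f <- fold_assignment(pairs$trial, folds)
  cv <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- subset_pairs(pairs, which(assign_f != f))
    ho <- subset_pairs(pairs, which(assign_f == f))
    fit <- cwcnn_optimize(init(), tr, epochs, lr, batch_size, seed + f)
    pred <- cwcnn_forward_batch(fit$params, ho$X, ho$n_channels)$y *
      fit$params$y_scale
    cv[[f]] <- tibble(
      fold = f,
      dof = paste0("dof", seq_len(nrow(ho$Y))),
      cc = vapply(seq_len(nrow(ho$Y)), function(d) {
        pearson_cc(pred[d, ], ho$Y[d, ])
      }, numeric(1)),
      n_holdout = ho$n
    )
  }
  final <- cwcnn_optimize(init(), pairs, epochs, lr, batch_size, seed)
  structure(
    list(
      params = final$params,
      cv = dplyr::bind_rows(cv),
      loss = final$loss,
      config = list(
        folds = folds, epochs = epochs, lr = lr, batch_size = batch_size,
        activation = activation, seed = seed, mode = "initial"
      )
    ),
    class = "cwcnn_fit"
  )
}

#' Recalibrate by layer transfer (frozen convolution)
#'
#' Session-to-session transfer: the convolutional filters — which see the
#' raw temporal structure of the envelope and carry over between days — are
#' frozen bit-exactly, and only the fully connected layer is re-trained on
#' the new session's pairs (warm-started from the existing weights), with
#' grouped k-fold cross-validation (default 5).
#'
#' @param fit A `cwcnn_fit` (or bare `cwcnn_params`).
#' @param pairs New-session [pair_windows()] result.
#' @inheritParams train_cwcnn
#' @return A `cwcnn_fit` whose `params$conv_w`/`conv_b` are identical to the
#'   input's.
#' @export
transfer_cwcnn <- function(fit, pairs, folds = 5, epochs = 100, lr = 1e-3,
                           batch_size = 128, seed = 1) {
  params <- if (inherits(fit, "cwcnn_fit")) fit$params else fit
  stopifnot(inherits(params, "cwcnn_params"), folds >= 2)
  assign_f <- fold_assignment(pairs$trial, folds)
  cv <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- subset_pairs(pairs, which(assign_f != f))
    ho <- subset_pairs(pairs, which(assign_f == f))
    upd <- cwcnn_optimize(params, tr, epochs, lr, batch_size, seed + f,
                          freeze_conv = TRUE)
    pred <- cwcnn_forward_batch(upd$params, ho$X, ho$n_channels)$y *
      upd$params$y_scale
    cv[[f]] <- tibble(
      fold = f,
      dof = paste0("dof", seq_len(nrow(ho$Y))),
      cc = vapply(seq_len(nrow(ho$Y)), function(d) {
        pearson_cc(pred[d, ], ho$Y[d, ])
      }, numeric(1)),
      n_holdout = ho$n
    )
  }
  final <- cwcnn_optimize(params, pairs, epochs, lr, batch_size, seed,
                          freeze_conv = TRUE)
  stopifnot(identical(final$params$conv_w, params$conv_w))
  structure(
    list(
      params = final$params,
      cv = dplyr::bind_rows(cv),
      loss = final$loss,
      config = list(
        folds = folds, epochs = epochs, lr = lr, batch_size = batch_size,
        activation = params$activation, seed = seed, mode = "transfer"
      )
    ),
    class = "cwcnn_fit"
  )
}

#' Predict joint angles for a set of windows
#'
#' @param object A `cwcnn_fit`.
#' @param pairs A `training_pairs` object (targets, if present, are
#'   ignored).
#' @param ... Unused.
#' @return Tibble with `time` and predicted `dof1..3` (degrees).
#' @export
predict.cwcnn_fit <- function(object, pairs, ...) {
  y <- cwcnn_forward_batch(object$params, pairs$X, pairs$n_channels)$y *
    object$params$y_scale
  out <- tibble(time = pairs$t_end)
  for (d in seq_len(nrow(y))) out[[paste0("dof", d)]] <- y[d, ]
  out
}

#' @export
print.cwcnn_fit <- function(x, ...) {
  cc <- tapply(x$cv$cc, x$cv$dof, mean)
  cat(sprintf(
    "<cwcnn_fit> %s, %d-fold CV mean held-out CC: %s\n",
    x$config$mode, x$config$folds,
    paste(sprintf("%s=%.3f", names(cc), cc), collapse = " ")
  ))
  invisible(x)
}

#' Per-fold cross-validation accuracy of a fitted CW-CNN
#'
#' @param x A `cwcnn_fit`.
#' @param ... Unused.
#' @return Tibble with columns `fold`, `dof`, `cc`, `n_holdout`.
#' @method tidy cwcnn_fit
#' @export
tidy.cwcnn_fit <- function(x, ...) x$cv

#' One-row summary of a fitted CW-CNN
#'
#' @param x A `cwcnn_fit`.
#' @param ... Unused.
#' @return One-row tibble: mean held-out CC per DOF, overall mean CC, final
#'   training loss, fold/epoch counts.
#' @method glance cwcnn_fit
#' @export
glance.cwcnn_fit <- function(x, ...) {
  cc <- tapply(x$cv$cc, x$cv$dof, mean)
  out <- tibble(
    cc_mean = mean(x$cv$cc), loss = x$loss,
    folds = x$config$folds, epochs = x$config$epochs, mode = x$config$mode
  )
  for (d in names(cc)) out[[paste0("cc_", d)]] <- unname(cc[d])
  out
}

#' Save / load a fitted CW-CNN as versioned JSON
#'
#' The container stores every weight array with its shape, the activation
#' tag, the target scale and the training config; a load/save round trip is
#' bit-exact (doubles serialized at full precision).
#'
#' @param fit A `cwcnn_fit` or `cwcnn_params`.
#' @param path File path.
#' @return `write_cwcnn` returns `path` invisibly; `read_cwcnn` returns a
#'   `cwcnn_fit`.
#' @export
write_cwcnn <- function(fit, path) {
  params <- if (inherits(fit, "cwcnn_fit")) fit$params else fit
  obj <- list(
    format = "semgdecode-cwcnn", version = 1L,
    activation = params$activation, y_scale = params$y_scale,
    conv_w = list(dim = dim(params$conv_w), data = as.numeric(params$conv_w)),
    conv_b = as.numeric(params$conv_b),
    fc_w = list(dim = dim(params$fc_w), data = as.numeric(params$fc_w)),
    fc_b = as.numeric(params$fc_b),
    config = if (inherits(fit, "cwcnn_fit")) fit$config else NULL,
    cv = if (inherits(fit, "cwcnn_fit")) fit$cv else NULL
  )
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cwcnn
#' @export
read_cwcnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "semgdecode-cwcnn")) {
    abort("Not a semgdecode CW-CNN container.")
  }
  params <- structure(
    list(
      conv_w = matrix(obj$conv_w$data, nrow = obj$conv_w$dim[1]),
      conv_b = as.numeric(obj$conv_b),
      fc_w = matrix(obj$fc_w$data, nrow = obj$fc_w$dim[1]),
      fc_b = as.numeric(obj$fc_b),
      activation = obj$activation,
      y_scale = obj$y_scale
    ),
    class = "cwcnn_params"
  )
  structure(
    list(
      params = params,
      cv = if (!is.null(obj$cv)) as_tibble(obj$cv) else NULL,
      loss = NA_real_,
      config = obj$config
    ),
    class = "cwcnn_fit"
  )
}
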