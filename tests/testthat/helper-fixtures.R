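# Shared fixtures, built in code at test time.

emg_channel_names <- function(n = 32) sprintf("ch%02d", seq_len(n))
emg_columns_test <- function(df) grep("^ch[0-9]+$", names(df), value = TRUE)

# short FIR for tests where the default 101-tap filter is overkill
short_fir <- function(taps = c(0.25, 0.5, 0.25)) {
  fir_lowpass(coefficients = taps)
}

# a small simulated session: `trials` trials cycling through all motions
small_session <- function(trials = 2, hold = 0.9, rest = 0.4, seed = 7,
                          model = synergy_model()) {
  scripts <- replicate(trials, trial_script(hold = hold, rest = rest),
                       simplify = FALSE)
  ses <- simulate_session(scripts, model, seed = seed)
  ses$scripts <- scripts
  ses$model <- model
  ses
}

# normalized IEMG stream (with trial column) + profile for a session
session_iemg <- function(ses, spec = fir_lowpass()) {
  profile <- compute_mvc_profile(ses$mvc, spec)
  iemg <- process_stream(ses$emg, profile, spec)
  iemg$trial <- ses$emg$trial
  list(iemg = iemg, profile = profile)
}

# independent brute-force CW-CNN forward pass: explicit double loop over
# (filter, channel) dot products, no shared code with the implementation
brute_force_forward <- function(params, window) {
  nf <- nrow(params$conv_w)
  nc <- ncol(window)
  feats <- numeric(nf * nc)
  idx <- 1
  for (j in seq_len(nf)) {
    for (c in seq_len(nc)) {
      z <- sum(params$conv_w[j, ] * window[, c]) + params$conv_b[j]
      if (params$activation == "relu" && z < 0) z <- 0
      feats[idx] <- z
      idx <- idx + 1
    }
  }
  out <- numeric(nrow(params$fc_w))
  for (d in seq_along(out)) {
    out[d] <- sum(params$fc_w[d, ] * feats) + params$fc_b[d]
  }
  out * params$y_scale
}

# independent TAC oracle: per-sample inside flags + run-length scan per
# posture, advancing through the posture list
brute_force_tac <- function(trajectory, config) {
  t <- trajectory$time - trajectory$time[1]
  keep <- t <= config$trial_limit + 1e-9
  t <- t[keep]
  ang <- as.matrix(trajectory[keep, c("dof1", "dof2", "dof3")])
  targets <- as.matrix(config$postures[, c("dof1", "dof2", "dof3")])
  n_post <- nrow(targets)
  t_complete <- rep(NA_real_, n_post)
  start <- 1L
  for (p in seq_len(n_post)) {
    if (start > length(t)) break
    inside <- vapply(start:length(t), function(i) {
      all(abs(ang[i, ] - targets[p, ]) <= config$tolerance)
    }, logical(1))
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    begins <- ends - r$lengths + 1L
    done <- FALSE
    for (k in which(r$values)) {
      i0 <- start + begins[k] - 1L
      i1 <- start + ends[k] - 1L
      t_entry <- t[i0]
      hit <- which(t[i0:i1] - t_entry >= config$dwell)
      if (length(hit) > 0) {
        t_done <- t_entry + config$dwell
        if (t_done <= config$trial_limit) {
          t_complete[p] <- t_done
          start <- i0 + hit[1] - 1L + 1L # sample after the completing one
          done <- TRUE
          break
        }
      }
    }
    if (!done) break
  }
  t_complete
}

# classical permutation test for the one-way ANOVA F statistic
permutation_anova_p <- function(groups, n_perm = 2000, seed = 1) {
  values <- unlist(groups)
  labels <- rep(seq_along(groups), lengths(groups))
  f_obs <- one_way_anova(groups)$f
  hits <- withr_seed_local(seed, {
    sum(replicate(n_perm, {
      lab <- sample(labels)
      one_way_anova(split(values, lab))$f >= f_obs
    }))
  })
  (hits + 1) / (n_perm + 1)
}

withr_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
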