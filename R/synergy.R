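#' Muscle-synergy forward model for synthetic sEMG
#'
#' Defines how six virtual muscle activations project onto the envelopes of
#' 32 electrode channels: a nonnegative 32 x 6 mixing matrix plus a constant
#' baseline envelope. The default mixing gives each virtual muscle a smooth
#' spatial tuning curve over a band of adjacent channels (emulating an
#' electrode sleeve over overlapping muscle bellies) with light cross-talk.
#'
#' @param n_channels Number of electrode channels (default 32).
#' @param baseline_noise Baseline envelope amplitude present at rest
#'   (arbitrary units, default 0.05).
#' @param gain_jitter Multiplicative log-normal jitter (sdlog) applied to
#'   per-channel gains; 0 keeps the deterministic default. Used to emulate a
#'   re-donned sleeve in transfer-learning experiments.
#' @param channel_shift Integer circular shift of the channel-to-muscle map,
#'   emulating sleeve rotation between sessions.
#' @param seed RNG seed for `gain_jitter` (required when `gain_jitter > 0`).
#' @return An object of class `synergy_model`: list with `mixing`
#'   (32 x 6 nonnegative matrix, columns named as in
#'   [angles_to_activations()]) and `baseline_noise`.
#' @export
#' @examples
#' m <- synergy_model()
#' dim(m$mixing)
synergy_model <- function(n_channels = 32, baseline_noise = 0.05,
                          gain_jitter = 0, channel_shift = 0, seed = NULL) {
  stopifnot(n_channels >= 6, baseline_noise >= 0, gain_jitter >= 0)
  muscles <- c("flex", "ext", "pron", "sup", "grip", "open")
  centers <- (seq_along(muscles) - 0.5) / length(muscles) * n_channels
  ch <- seq_len(n_channels)
  mixing <- sapply(centers, function(c0) {
    # circular distance over the sleeve circumference
    d <- pmin(abs(ch - c0), n_channels - abs(ch - c0))
    0.9 * exp(-(d / (n_channels / 10))^2) + 0.05
  })
  colnames(mixing) <- muscles
  if (channel_shift != 0) {
    shift <- ((ch - 1 + channel_shift) %% n_channels) + 1
    mixing <- mixing[shift, , drop = FALSE]
  }
  if (gain_jitter > 0) {
    if (is.null(seed)) abort("`seed` is required when `gain_jitter` > 0.")
    gains <- withr_seed(seed, exp(rnorm(n_channels, sd = gain_jitter)))
    mixing <- mixing * gains
  }
  structure(
    list(mixing = mixing, baseline_noise = baseline_noise),
    class = "synergy_model"
  )
}

# evaluate an expression under a temporary RNG seed, restoring state after
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Noise-free per-channel envelope implied by activations
#'
#' The envelope is the linear synergy mixture `mixing %*% activation` plus
#' the baseline; superposition holds exactly. Used both by the generator and
#' by tests that check linearity of the forward model.
#'
#' @param activations Activation tibble from [angles_to_activations()] (or
#'   any tibble with the six muscle columns).
#' @param model A [synergy_model()].
#' @return Numeric matrix, rows = time points, columns = channels.
#' @export
activation_envelope <- function(activations, model) {
  act <- as.matrix(activations[, colnames(model$mixing), drop = FALSE])
  env <- act %*% t(model$mixing) + model$baseline_noise
  colnames(env) <- emg_channel_names(nrow(model$mixing))
  env
}

emg_channel_names <- function(n = 32) sprintf("ch%02d", seq_len(n))

resample_columns <- function(df, new_time) {
  cols <- setdiff(names(df), "time")
  out <- tibble(time = new_time)
  for (cn in cols) {
    out[[cn]] <- approx(df$time, df[[cn]], xout = new_time, rule = 2)$y
  }
  out
}

#' Synthesize a raw multichannel sEMG stream
#'
#' Generates amplitude-modulated noise: each channel is a zero-mean,
#' unit-variance white Gaussian carrier multiplied by that channel's
#' synergy envelope. Activations sampled at a lower rate (e.g. the 120 Hz
#' motion-capture rate) are linearly interpolated onto the EMG clock.
#'
#' @param activations Activation tibble ([angles_to_activations()]).
#' @param model A [synergy_model()].
#' @param rate EMG sampling rate in Hz (default 500).
#' @param seed Integer seed; required so streams are reproducible.
#' @return A tibble with `time` plus one column per channel (`ch01` ...),
#'   with attribute `rate`.
#' @export
synthesize_emg <- function(activations, model, rate = 500, seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: synthetic sEMG must be reproducible.")
  }
  stopifnot(rate > 0)
  t_end <- max(activations$time)
  new_time <- seq(0, t_end, by = 1 / rate)
  act <- resample_columns(activations, new_time)
  env <- activation_envelope(act, model)
  carrier <- withr_seed(seed, matrix(rnorm(length(env)), nrow = nrow(env)))
  samples <- carrier * env
  out <- tibble(time = new_time)
  out[colnames(env)] <- as_tibble(samples, .name_repair = "minimal")
  attr(out, "rate") <- rate
  out
}

#' Synthesize a maximum voluntary contraction (MVC) recording
#'
#' Produces the calibration recording the normalizer keys on: a rest
#' lead-in, a sustained burst with every virtual muscle at full activation
#' (per-channel envelope = row sum of the mixing matrix + baseline), and a
#' rest tail. The rest segments let the integrated-MVC minimum capture the
#' baseline envelope while the burst sets the per-channel maximum.
#'
#' @param model A [synergy_model()].
#' @param duration Total recording length in seconds (default 6).
#' @param rest Rest length at each end in seconds (default 1).
#' @param rate Sampling rate in Hz (default 500).
#' @param seed Integer seed (required).
#' @return A raw EMG tibble as from [synthesize_emg()].
#' @export
synthesize_mvc <- function(model, duration = 6, rest = 1, rate = 500, seed) {
  stopifnot(duration > 2 * rest, rest > 0)
  time <- seq(0, duration, by = 1 / rate)
  burst <- as.numeric(time >= rest & time <= duration - rest)
  act <- tibble(time = time)
  for (m in colnames(model$mixing)) act[[m]] <- burst
  synthesize_emg(act, model, rate = rate, seed = seed)
}

#' Simulate a full recording session
#'
#' Renders a script's angle trajectory, derives muscle activations, and
#' synthesizes the matching raw sEMG and an MVC calibration recording —
#' everything a decoding session needs, with ground truth attached.
#'
#' @param script A `motion_script` (or list of scripts, one per trial).
#' @param model A [synergy_model()].
#' @param seed Integer seed; trial t uses `seed + t` offsets internally.
#' @param angle_rate Motion-capture rate in Hz (default 120).
#' @param emg_rate EMG rate in Hz (default 500).
#' @param amplitude Plateau amplitude in degrees (default 30).
#' @param mvc_seed Seed for the MVC recording (default `seed + 1000`).
#' @return A list with `emg`, `angles` (both with a `trial` column when
#'   multiple scripts are given), and `mvc`.
#' @export
simulate_session <- function(script, model, seed, angle_rate = 120,
                             emg_rate = 500, amplitude = 30,
                             mvc_seed = seed + 1000) {
  scripts <- if (inherits(script, "motion_script")) list(script) else script
  emg_all <- vector("list", length(scripts))
  ang_all <- vector("list", length(scripts))
  offset <- 0
  for (i in seq_along(scripts)) {
    ang <- render_angle_trajectory(scripts[[i]], rate = angle_rate,
                                   amplitude = amplitude)
    act <- angles_to_activations(ang, max_angle = amplitude)
    emg <- synthesize_emg(act, model, rate = emg_rate, seed = seed + i)
    ang$trial <- i
    emg$trial <- i
    ang$time <- ang$time + offset
    emg$time <- emg$time + offset
    offset <- offset + max(scripts[[i]]$t_end)
    ang_all[[i]] <- ang
    emg_all[[i]] <- emg
  }
  list(
    emg = dplyr::bind_rows(emg_all),
    angles = dplyr::bind_rows(ang_all),
    mvc = synthesize_mvc(model, seed = mvc_seed, rate = emg_rate)
  )
}
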