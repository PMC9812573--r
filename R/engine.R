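#' File-backed replay stream source
#'
#' Wraps a recorded raw EMG stream as the source the real-time loop polls.
#' Replay is driven by a simulated clock: the source exposes every sample
#' with `time <= clock`, and the loop advances the clock by its cycle
#' period, so results are machine-speed independent and bit-reproducible.
#'
#' @param emg Raw EMG tibble (`time` + channel columns).
#' @return Object of class `replay_source`.
#' @export
replay_source <- function(emg) {
  ch <- emg_columns(emg)
  if (length(ch) == 0) abort("Stream has no channel columns (ch01...).")
  if (any(diff(emg$time) <= 0)) abort("Timestamps must be strictly increasing.")
  structure(
    list(time = emg$time, samples = as.matrix(emg[, ch]), n = nrow(emg)),
    class = "replay_source"
  )
}

#' Real-time engine configuration
#'
#' @param window_ms Acquisition window length in ms (default 120).
#' @param emg_rate EMG sampling rate in Hz (default 500); `window_ms *
#'   emg_rate / 1000` must be an integer (60 here).
#' @param channels Electrode channel count (default 32).
#' @param cycle_ms Simulated processing period per cycle in ms (default
#'   120): samples arriving within a cycle are skipped, implementing the
#'   latest-window lossy policy.
#' @param kalman List of arguments passed to [kalman_init()].
#' @return Object of class `engine_config`.
#' @export
engine_config <- function(window_ms = 120, emg_rate = 500, channels = 32,
                          cycle_ms = 120, kalman = list()) {
  n_win <- window_ms * emg_rate / 1000
  if (abs(n_win - round(n_win)) > 1e-9) {
    abort("window_ms * emg_rate must be an integer number of samples.")
  }
  structure(
    list(
      window_ms = window_ms, emg_rate = emg_rate, channels = channels,
      window_len = as.integer(round(n_win)), cycle_ms = cycle_ms,
      kalman = kalman
    ),
    class = "engine_config"
  )
}

#' Grab the latest full window from a source
#'
#' Returns the most recent `window_len` samples with `time <= clock`.
#' Samples that arrived while a previous cycle was busy are simply never
#' windowed (lossy, latest-window policy), mirroring a live loop that
#' always jumps to the freshest data.
#'
#' @param source A [replay_source()].
#' @param config An [engine_config()].
#' @param clock Current simulated time (s); defaults to the end of the
#'   stream.
#' @return List with `samples` (window_len x channels matrix), `t_start`,
#'   `t_end`, and `end_index` into the source.
#' @export
grab_latest_window <- function(source, config, clock = Inf) {
  avail <- sum(source$time <= clock)
  if (avail < config$window_len) {
    abort(sprintf("Stream underrun: %d samples available, %d needed.",
                  avail, config$window_len))
  }
  idx <- (avail - config$window_len + 1L):avail
  list(
    samples = source$samples[idx, , drop = FALSE],
    t_start = source$time[idx[1]],
    t_end = source$time[avail],
    end_index = avail
  )
}

new_engine <- function(fit, profile, spec = fir_lowpass(),
                       config = engine_config()) {
  params <- if (inherits(fit, "cwcnn_fit")) fit$params else fit
  structure(
    list(
      params = params, profile = profile, spec = spec, config = config,
      kstates = NULL
    ),
    class = "semg_engine"
  )
}

# one decode cycle on an already-grabbed window; returns angles + latency.
# The latency clock wraps exactly the three stages: signal, model, kalman.
engine_cycle <- function(engine, window, history) {
  t0 <- proc.time()[["elapsed"]]
  nb <- length(engine$spec$coefficients)
  state <- rectify(history) # last nb-1 raw samples before the window
  proc <- process_window(window, engine$profile, engine$spec, state = state)
  iemg_win <- proc$values
  raw_angles <- cwcnn_forward(engine$params, iemg_win)
  if (is.null(engine$kstates)) {
    engine$kstates <- lapply(seq_along(raw_angles), function(i) {
      do.call(kalman_init, engine$config$kalman)
    })
  }
  smoothed <- numeric(length(raw_angles))
  for (d in seq_along(raw_angles)) {
    st <- engine$kstates[[d]]
    p_prev <- st$P
    stepped <- kf_step(st, raw_angles[[d]])
    st <- stepped$state
    if (st$adapt) st <- adapt_qr(st, p_prev)
    engine$kstates[[d]] <- st
    smoothed[d] <- stepped$x
  }
  t1 <- proc.time()[["elapsed"]]
  list(
    engine = engine, raw = unname(raw_angles), smoothed = smoothed,
    latency_ms = max((t1 - t0) * 1000, 0)
  )
}

#' Replay a recorded session through the real-time loop
#'
#' Repeatedly grabs the latest 120 ms window from the source, runs the
#' three decode stages (IEMG processing, CW-CNN regression, adaptive Kalman
#' smoothing) and records the wall-clock computational latency of exactly
#' those stages. The simulated clock starts when the first full window is
#' available and advances by `cycle_ms` per cycle; a failed cycle is logged
#' and skipped rather than aborting the session.
#'
#' Filtering state for each grabbed window is reconstructed from the
#' source's sample history, so each cycle's output equals the offline
#' composition `process_window()` -> [cwcnn_forward()] -> [kf_step()] on
#' the same samples.
#'
#' @param fit A `cwcnn_fit` (or `cwcnn_params`).
#' @param source A [replay_source()] (or raw EMG tibble).
#' @param profile An [compute_mvc_profile()] result.
#' @param spec A [fir_lowpass()] specification.
#' @param config An [engine_config()].
#' @param duration Optional cap on simulated session length (s).
#' @return List with `angles` (tibble `time`, `cycle`, `dof1..3` smoothed,
#'   `raw_dof1..3` unsmoothed) and `latency` (tibble `cycle`, `time`,
#'   `duration_ms`).
#' @export
run_session <- function(fit, source, profile, spec = fir_lowpass(),
                        config = engine_config(), duration = NULL) {
  if (is.data.frame(source)) source <- replay_source(source)
  if (source$n == 0) abort("Empty source: nothing to replay.")
  if (source$n < config$window_len) {
    abort("Source never accumulates a full window.")
  }
  engine <- new_engine(fit, profile, spec, config)
  nb <- length(spec$coefficients)
  cycle_s <- config$cycle_ms / 1000
  clock <- source$time[config$window_len] # first full window available
  t_stop <- if (is.null(duration)) Inf else source$time[1] + duration
  last_end <- 0L
  ang <- list(); lat <- list()
  cycle <- 0L
  while (clock <= min(max(source$time), t_stop)) {
    win <- grab_latest_window(source, config, clock)
    if (win$end_index > last_end) { # new data since the previous cycle
      cycle <- cycle + 1L
      hist_idx <- (win$end_index - config$window_len) - ((nb - 1L):1L) + 1L
      history <- matrix(0, nb - 1L, ncol(source$samples))
      ok <- hist_idx >= 1L
      if (any(ok)) {
        history[ok, ] <- source$samples[hist_idx[ok], , drop = FALSE]
      }
      res <- tryCatch(
        engine_cycle(engine, win$samples, history),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        warning(sprintf("Cycle %d failed and was skipped: %s",
                        cycle, conditionMessage(res)), call. = FALSE)
      } else {
        engine <- res$engine
        ang[[length(ang) + 1]] <- c(win$t_end, cycle, res$smoothed, res$raw)
        lat[[length(lat) + 1]] <- c(cycle, win$t_end, res$latency_ms)
        last_end <- win$end_index
      }
    }
    clock <- clock + cycle_s
  }
  if (length(ang) == 0) abort("Session produced no cycles.")
  amat <- do.call(rbind, ang)
  n_dof <- (ncol(amat) - 2L) / 2L
  angles <- tibble(time = amat[, 1], cycle = as.integer(amat[, 2]))
  for (d in seq_len(n_dof)) angles[[paste0("dof", d)]] <- amat[, 2 + d]
  for (d in seq_len(n_dof)) {
    angles[[paste0("raw_dof", d)]] <- amat[, 2 + n_dof + d]
  }
  lmat <- do.call(rbind, lat)
  list(
    angles = angles,
    latency = tibble(cycle = as.integer(lmat[, 1]), time = lmat[, 2],
                     duration_ms = lmat[, 3])
  )
}
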