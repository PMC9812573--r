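#' Target achievement control (TAC) test configuration
#'
#' A TAC trial cues a sequence of target postures; a posture is achieved
#' when all three DOFs are simultaneously within the tolerance of the
#' target, and completed after a *continuous* in-tolerance dwell. The three
#' standard trials share the parameters: 3 DOFs, 0.5 s dwell, +/-5 deg
#' tolerance, 30 s trial limit, and four postures from the central position
#' through two targets back to central.
#'
#' @param test One of `"TAC-1"`, `"TAC-2"`, `"TAC-3"`, or `"custom"`.
#' @param postures For `test = "custom"`: tibble with columns `posture`,
#'   `dof1`, `dof2`, `dof3` (degrees), in order.
#' @param dwell Continuous dwell time required (s, default 0.5).
#' @param tolerance Acceptance half-width per DOF (degrees, default 5).
#' @param trial_limit Trial time limit (s, default 30).
#' @return Object of class `tac_config`.
#' @export
#' @examples
#' tac_config("TAC-1")$postures
tac_config <- function(test = c("TAC-1", "TAC-2", "TAC-3", "custom"),
                       postures = NULL, dwell = 0.5, tolerance = 5,
                       trial_limit = 30) {
  test <- match.arg(test)
  stopifnot(tolerance > 0, dwell > 0, dwell < trial_limit)
  if (test != "custom") {
    sign1 <- switch(test, "TAC-1" = 1, "TAC-2" = -1, "TAC-3" = 1)
    sign2 <- switch(test, "TAC-1" = 1, "TAC-2" = 1, "TAC-3" = -1)
    postures <- tibble(
      posture = c("Central 1", "Target 1", "Target 2", "Central 2"),
      dof1 = c(0, 15, 30, 0) * sign1,
      dof2 = c(0, 15, 30, 0) * sign2,
      dof3 = c(0, 15, 30, 0)
    )
  }
  stopifnot(is.data.frame(postures), nrow(postures) >= 1)
  structure(
    list(test = test, postures = as_tibble(postures), dwell = dwell,
         tolerance = tolerance, trial_limit = trial_limit),
    class = "tac_config"
  )
}

#' Evaluate a TAC trial from a controlled trajectory
#'
#' Runs the TAC state machine over the 3-DOF trajectory: starting with the
#' first posture, a sample is "inside" when every DOF is within
#' `tolerance` of the target (closed interval); a continuous inside run of
#' at least `dwell` seconds completes the posture (completion time = entry
#' time + dwell) and the next posture becomes active from the following
#' sample. Leaving tolerance resets the dwell timer. The trial ends when
#' the last posture completes or at `trial_limit`.
#'
#' @param trajectory Tibble `time`, `dof1..3` (degrees), e.g. the smoothed
#'   engine output. Time is measured from the first sample.
#' @param config A [tac_config()].
#' @return Object of class `tac_result`: list with `postures` (tibble:
#'   `posture`, targets, `achieved`, `t_complete`), `dwells` (tibble of
#'   in-tolerance intervals for the active posture), `trial_time`
#'   (completion of the final posture, or `trial_limit` on timeout),
#'   `config` and the clipped `trajectory`.
#' @export
tac_evaluate <- function(trajectory, config = tac_config("TAC-1")) {
  t <- trajectory$time - trajectory$time[1]
  keep <- t <= config$trial_limit + 1e-9
  if (sum(keep) < 2) abort("Trajectory too short to evaluate.")
  t <- t[keep]
  ang <- as.matrix(trajectory[keep, c("dof1", "dof2", "dof3")])
  targets <- as.matrix(config$postures[, c("dof1", "dof2", "dof3")])
  n_post <- nrow(targets)

  achieved <- rep(FALSE, n_post)
  t_complete <- rep(NA_real_, n_post)
  dwells <- list()
  cur <- 1L
  run_start <- NA_real_
  i <- 1L
  while (i <= length(t) && cur <= n_post) {
    inside <- all(abs(ang[i, ] - targets[cur, ]) <= config$tolerance)
    if (inside) {
      if (is.na(run_start)) run_start <- t[i]
      if (t[i] - run_start >= config$dwell) {
        done_at <- run_start + config$dwell
        if (done_at <= config$trial_limit) {
          achieved[cur] <- TRUE
          t_complete[cur] <- done_at
          dwells[[length(dwells) + 1]] <- tibble(
            posture = config$postures$posture[cur],
            t_enter = run_start, t_complete = done_at
          )
          cur <- cur + 1L
          run_start <- NA_real_
        }
      }
    } else {
      run_start <- NA_real_
    }
    i <- i + 1L
  }
  if (!all(achieved) && max(t) < config$trial_limit - 1e-9) {
    abort(paste0(
      "Trajectory ends before the trial limit with postures still open; ",
      "cover the full trial or complete every posture."
    ))
  }
  structure(
    list(
      postures = dplyr::bind_cols(
        config$postures,
        tibble(achieved = achieved, t_complete = t_complete)
      ),
      dwells = if (length(dwells)) dplyr::bind_rows(dwells) else
        tibble(posture = character(), t_enter = numeric(),
               t_complete = numeric()),
      trial_time = if (all(achieved)) max(t_complete) else config$trial_limit,
      config = config,
      trajectory = tibble(time = t, dof1 = ang[, 1], dof2 = ang[, 2],
                          dof3 = ang[, 3])
    ),
    class = "tac_result"
  )
}

#' @export
print.tac_result <- function(x, ...) {
  done <- sum(x$postures$achieved)
  cat(sprintf("<tac_result> %s: %d/%d postures, trial time %.2f s\n",
              x$config$test, done, nrow(x$postures), x$trial_time))
  invisible(x)
}

#' Completion-rate curve of a TAC trial
#'
#' `CR(t) = N_completed(t) / N_postures`: the fraction of the trial's
#' postures completed by time `t`, a right-continuous nondecreasing step
#' function on `[0, trial_limit]`.
#'
#' @param result A [tac_evaluate()] result.
#' @return Tibble (`time`, `cr`) listing the step change points, starting
#'   at `(0, 0)` and ending at `trial_limit`.
#' @export
completion_rate_curve <- function(result) {
  n_post <- nrow(result$postures)
  tc <- sort(result$postures$t_complete[result$postures$achieved])
  steps <- tibble(
    time = c(0, tc, result$config$trial_limit),
    cr = c(0, seq_along(tc), length(tc)) / n_post
  )
  steps[!duplicated(steps$time, fromLast = TRUE), ]
}

#' Evaluate the completion rate at given times
#'
#' @param result A [tac_evaluate()] result.
#' @param times Numeric vector of times (s).
#' @return `CR(times)`, right-continuous.
#' @export
completion_rate_at <- function(result, times) {
  tc <- sort(result$postures$t_complete[result$postures$achieved])
  vapply(times, function(tt) sum(tc <= tt), numeric(1)) /
    nrow(result$postures)
}

#' Ideal trajectory for a TAC trial
#'
#' Renders a trajectory that jumps to each target posture (after a travel
#' time) and holds it: the reference input used to exercise the TAC state
#' machine without a human in the loop.
#'
#' @param config A [tac_config()].
#' @param hold Hold duration at each posture (s); must exceed `dwell`.
#' @param travel Travel time between postures (s).
#' @param rate Sample rate (Hz).
#' @return Tibble `time`, `dof1..3`.
#' @export
tac_reference_trajectory <- function(config, hold = 0.6, travel = 0.5,
                                     rate = 50) {
  targets <- as.matrix(config$postures[, c("dof1", "dof2", "dof3")])
  segs <- list()
  t0 <- 0
  for (j in seq_len(nrow(targets))) {
    if (j > 1) {
      # linear travel between postures (outside tolerance most of the way)
      tt <- seq(0, travel, by = 1 / rate)[-1]
      w <- tt / travel
      segs[[length(segs) + 1]] <- tibble(
        time = t0 + tt,
        dof1 = (1 - w) * targets[j - 1, 1] + w * targets[j, 1],
        dof2 = (1 - w) * targets[j - 1, 2] + w * targets[j, 2],
        dof3 = (1 - w) * targets[j - 1, 3] + w * targets[j, 3]
      )
      t0 <- t0 + travel
    }
    tt <- seq(0, hold, by = 1 / rate)
    if (j > 1) tt <- tt[-1]
    segs[[length(segs) + 1]] <- tibble(
      time = t0 + tt, dof1 = targets[j, 1], dof2 = targets[j, 2],
      dof3 = targets[j, 3]
    )
    t0 <- t0 + hold
  }
  dplyr::bind_rows(segs)
}
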