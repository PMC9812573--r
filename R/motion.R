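#' Catalogue of scripted daily motions
#'
#' The pipeline works with 14 scripted hand/wrist motions: rest (`M0`), five
#' single motions (`M1`-`M5`), four double-mixture motions (`M6`-`M9`) and
#' four triple-mixture motions (`M10`-`M13`). Each motion is a signed unit
#' direction on the three degrees of freedom (DOF1 wrist flexion +/extension -,
#' DOF2 pronation +/supination -, DOF3 hand grip, nonnegative); rendering a
#' script scales these directions by the plateau amplitude.
#'
#' @return A tibble with columns `motion` (e.g. `"M1"`), `label`,
#'   `class` (`"rest"`, `"single"`, `"double"`, `"triple"`) and signed unit
#'   targets `dof1`, `dof2`, `dof3`.
#' @export
#' @examples
#' motion_catalogue()
motion_catalogue <- function() {
  tibble(
    motion = paste0("M", 0:13),
    label = c(
      "Rest", "Wrist flexion", "Wrist extension", "Wrist pronation",
      "Wrist supination", "Hand grip", "WF+HG", "WE+HG", "WP+HG", "WS+HG",
      "WF+WP+HG", "WE+WP+HG", "WF+WS+HG", "WE+WS+HG"
    ),
    class = c(
      "rest", rep("single", 5), rep("double", 4), rep("triple", 4)
    ),
    dof1 = c(0, 1, -1, 0, 0, 0, 1, -1, 0, 0, 1, -1, 1, -1),
    dof2 = c(0, 0, 0, 1, -1, 0, 0, 0, 1, -1, 1, 1, -1, -1),
    dof3 = c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 1)
  )
}

#' Build a motion script
#'
#' A motion script is an ordered list of (motion id, duration) entries that a
#' subject would be cued through: e.g. rest, then each motion held for a fixed
#' time. Scripts drive both the ground-truth angle trajectory and the
#' synthetic sEMG generator.
#'
#' @param motion Character vector of motion ids (`"M0"` .. `"M13"`).
#' @param duration Numeric vector of positive durations in seconds (recycled
#'   to `length(motion)` if scalar).
#' @return A tibble of class `motion_script` with columns `motion`,
#'   `duration`, `t_start`, `t_end`.
#' @export
#' @examples
#' motion_script(c("M0", "M1", "M0"), c(1, 2, 1))
motion_script <- function(motion, duration) {
  if (length(duration) == 1L) duration <- rep(duration, length(motion))
  if (length(motion) != length(duration)) {
    abort("`motion` and `duration` must have the same length.")
  }
  bad <- setdiff(motion, motion_catalogue()$motion)
  if (length(bad) > 0) {
    abort(paste0("Unknown motion id(s): ", paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(duration)) || any(duration <= 0)) {
    abort("All durations must be finite and > 0.")
  }
  out <- tibble(
    motion = as.character(motion),
    duration = as.numeric(duration),
    t_end = cumsum(as.numeric(duration))
  )
  out$t_start <- out$t_end - out$duration
  out <- out[, c("motion", "duration", "t_start", "t_end")]
  class(out) <- c("motion_script", class(out))
  out
}

#' Standard one-trial script cycling through all motions
#'
#' Convenience constructor for the trial structure used throughout: rest,
#' then each of M1-M13 held for `hold` seconds, then rest again.
#'
#' @param hold Hold duration per motion (s).
#' @param rest Rest duration at the start and end (s).
#' @return A `motion_script`.
#' @export
trial_script <- function(hold = 1, rest = 0.5) {
  motion_script(c("M0", paste0("M", 1:13), "M0"),
                c(rest, rep(hold, 13), rest))
}

#' Render a motion script as a 3-DOF joint-angle trajectory
#'
#' Produces the ground-truth angle stream a motion-capture system would
#' record for a subject following `script`: each entry is a plateau at the
#' motion's target angles, with a raised-cosine ramp of `ramp` seconds easing
#' into each new plateau so that "measured" angles have no step
#' discontinuities. Rest (`M0`) is the all-zero posture.
#'
#' @param script A `motion_script`.
#' @param rate Sampling rate in Hz (motion capture default 120).
#' @param amplitude Plateau amplitude in degrees applied to the unit targets
#'   (default 30).
#' @param ramp Transition ramp time in seconds (default 0.3).
#' @return A tibble with columns `time` (s), `dof1`, `dof2`, `dof3`
#'   (degrees), with attribute `rate`.
#' @export
#' @examples
#' traj <- render_angle_trajectory(motion_script("M1", 1))
#' range(traj$dof1)
render_angle_trajectory <- function(script, rate = 120, amplitude = 30,
                                    ramp = 0.3) {
  stopifnot(rate > 0, amplitude > 0, ramp >= 0)
  if (!inherits(script, "motion_script")) {
    script <- motion_script(script$motion, script$duration)
  }
  cat_tbl <- motion_catalogue()
  idx <- match(script$motion, cat_tbl$motion)
  targets <- as.matrix(cat_tbl[idx, c("dof1", "dof2", "dof3")]) * amplitude

  total <- sum(script$duration)
  time <- seq(0, total, by = 1 / rate)
  time <- time[time < total - 1e-12] # right-open: concatenated trials abut
  # which entry each timestamp falls in (right-open intervals)
  entry <- findInterval(time, script$t_start)
  entry[entry < 1L] <- 1L
  entry[entry > nrow(script)] <- nrow(script)

  ang <- targets[entry, , drop = FALSE]
  if (ramp > 0 && nrow(script) > 1) {
    for (j in 2:nrow(script)) {
      in_ramp <- entry == j & (time - script$t_start[j]) < ramp
      if (any(in_ramp)) {
        tau <- (time[in_ramp] - script$t_start[j]) / ramp
        w <- 0.5 * (1 - cos(pi * tau)) # 0 -> 1
        prev <- targets[j - 1L, ]
        cur <- targets[j, ]
        ang[in_ramp, ] <- outer(1 - w, prev) + outer(w, cur)
      }
    }
  }
  out <- tibble(time = time, dof1 = ang[, 1], dof2 = ang[, 2], dof3 = ang[, 3])
  attr(out, "rate") <- rate
  out
}

#' Map joint angles to virtual muscle activations
#'
#' Converts a 3-DOF angle stream into activations of six virtual muscles, one
#' agonist/antagonist pair per DOF (flexor/extensor, pronator/supinator,
#' gripper/opener). Positive excursion on a DOF drives the agonist, negative
#' the antagonist, linearly rectified and scaled to `[0, 1]` at `max_angle`;
#' rest maps to all-zero activation.
#'
#' @param angles Angle tibble as from [render_angle_trajectory()].
#' @param max_angle Angle (degrees) at which activation saturates at 1.
#' @return A tibble with `time` and six activation columns
#'   `flex`, `ext`, `pron`, `sup`, `grip`, `open`, all in `[0, 1]`.
#' @export
angles_to_activations <- function(angles, max_angle = 30) {
  stopifnot(max_angle > 0)
  half <- function(x) pmin(pmax(x, 0) / max_angle, 1)
  tibble(
    time = angles$time,
    flex = half(angles$dof1), ext = half(-angles$dof1),
    pron = half(angles$dof2), sup = half(-angles$dof2),
    grip = half(angles$dof3), open = half(-angles$dof3)
  )
}
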