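#' Plot held-out CV accuracy of a fitted CW-CNN
#'
#' @param object A `cwcnn_fit`.
#' @param ... Unused.
#' @return A ggplot: per-fold held-out CC by DOF.
#' @method autoplot cwcnn_fit
#' @export
autoplot.cwcnn_fit <- function(object, ...) {
  ggplot2::ggplot(object$cv,
                  ggplot2::aes(x = .data$dof, y = .data$cc)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "held-out Pearson CC",
      title = sprintf("%d-fold cross-validation (%s)",
                      object$config$folds, object$config$mode)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the Q/R adaptation trace of a smoothed stream
#'
#' Shows the convergence of the adaptive covariances over iterations,
#' per DOF.
#'
#' @param smoothed A [kalman_smooth()] result (or its trace tibble).
#' @return A ggplot.
#' @export
plot_kalman_trace <- function(smoothed) {
  tr <- if (is.data.frame(smoothed) && all(c("k", "Q", "R") %in%
                                           names(smoothed))) {
    smoothed
  } else {
    kalman_trace(smoothed)
  }
  long <- tidyr::pivot_longer(tr[, c("dof", "k", "Q", "R")],
                              c("Q", "R"), names_to = "param")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value,
                                     colour = .data$dof)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~param, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = expression(deg^2),
                  title = "Adaptive Kalman covariance convergence") +
    ggplot2::theme_minimal()
}

#' Plot a TAC trial: trajectory, tolerance bands and completion-rate curve
#'
#' @param object A `tac_result`.
#' @param ... Unused.
#' @return A ggplot of the 3-DOF trajectory with target tolerance bands;
#'   completed dwell windows shaded.
#' @method autoplot tac_result
#' @export
autoplot.tac_result <- function(object, ...) {
  traj <- tidyr::pivot_longer(object$trajectory, -"time",
                              names_to = "dof", values_to = "angle")
  post <- object$postures
  bands <- tidyr::pivot_longer(
    post[, c("posture", "dof1", "dof2", "dof3")],
    -"posture", names_to = "dof", values_to = "target"
  )
  bands$lo <- bands$target - object$config$tolerance
  bands$hi <- bands$target + object$config$tolerance
  p <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$time, y = .data$angle)) +
    ggplot2::geom_hline(
      data = bands, ggplot2::aes(yintercept = .data$lo),
      colour = "red", linewidth = 0.2, alpha = 0.5
    ) +
    ggplot2::geom_hline(
      data = bands, ggplot2::aes(yintercept = .data$hi),
      colour = "red", linewidth = 0.2, alpha = 0.5
    ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~dof, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "angle (deg)",
                  title = sprintf("%s trial (%.1f s)", object$config$test,
                                  object$trial_time)) +
    ggplot2::theme_minimal()
  if (nrow(object$dwells) > 0) {
    dz <- object$dwells
    p <- p + ggplot2::geom_rect(
      data = dz, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$t_enter, xmax = .data$t_complete,
                   ymin = -Inf, ymax = Inf),
      fill = "green", alpha = 0.15
    )
  }
  p
}

#' Plot a completion-rate curve
#'
#' @param result A [tac_evaluate()] result (or a list of them, named by
#'   trial, to overlay).
#' @return A ggplot step plot of CR(t) on `[0, trial_limit]`.
#' @export
plot_completion_rate <- function(result) {
  results <- if (inherits(result, "tac_result")) {
    stats::setNames(list(result), result$config$test)
  } else {
    result
  }
  curves <- dplyr::bind_rows(
    lapply(names(results), function(nm) {
      cc <- completion_rate_curve(results[[nm]])
      cc$trial <- nm
      cc
    })
  )
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$cr,
                                       colour = .data$trial)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (s)", y = "completion rate",
                  title = "TAC completion-rate curve") +
    ggplot2::theme_minimal()
}
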