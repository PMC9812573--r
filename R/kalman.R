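#' Initialize a scalar adaptive Kalman filter state
#'
#' One independent scalar filter per DOF smooths the regressor's angle
#' stream. State `x` is the filtered angle (degrees), `P` the error
#' covariance, `Q`/`R` the transition and observation covariances (all
#' deg^2) and `k` the iteration count. `Q` and `R` can adapt online from
#' the innovation sequence (see [adapt_qr()]); floors keep them positive.
#'
#' @param q_init,r_init Initial transition / observation covariances
#'   (defaults 0.05 and 0.4 deg^2).
#' @param q_floor,r_floor Lower bounds applied to the adaptive variance
#'   estimates (defaults 1e-6, 1e-4 deg^2).
#' @param adapt Logical: update `Q`/`R` after each step (default TRUE).
#' @return Object of class `kalman_state`.
#' @export
kalman_init <- function(q_init = 0.05, r_init = 0.4,
                        q_floor = 1e-6, r_floor = 1e-4, adapt = TRUE) {
  stopifnot(q_init > 0, r_init > 0, q_floor > 0, r_floor > 0)
  structure(
    list(
      x = NA_real_, P = r_init, Q = q_init, R = r_init, k = 0L,
      q_floor = q_floor, r_floor = r_floor, adapt = adapt,
      K = NA_real_, d = NA_real_
    ),
    class = "kalman_state"
  )
}

#' One Kalman filter iteration
#'
#' Gain, state and covariance updates:
#' `K = P / (P + R)`; `x' = x + K (z - x)`; `P' = (1 - K) P + Q`.
#' The very first observation initializes `x = z` with no update (avoids a
#' startup transient toward zero). The innovation `d = z - x` and gain are
#' kept on the state for the adaptive update.
#'
#' @param state A `kalman_state`.
#' @param z New observation (degrees).
#' @return List with `state` (updated) and `x` (the filtered value).
#' @export
kf_step <- function(state, z) {
  if (!is.finite(z)) abort("Kalman step received a non-finite observation.")
  if (!is.finite(state$x)) {
    state$x <- z
    state$d <- 0
    state$K <- NA_real_
    return(list(state = state, x = z))
  }
  K <- state$P / (state$P + state$R)
  d <- z - state$x
  state$x <- state$x + K * d
  state$P <- (1 - K) * state$P + state$Q
  state$k <- state$k + 1L
  state$K <- K
  state$d <- d
  list(state = state, x = state$x)
}

#' Innovation-based adaptation of Q and R
#'
#' After each iteration the covariances move toward moment-matched
#' estimates computed from the innovation `d = z - x(k-1)`:
#' `R_hat = max(d^2 - P(k-1), r_floor)` and `Q_hat = max(K^2 d^2, q_floor)`,
#' blended by the iteration-count running mean
#' `Q(k+1) = Q(k) + (Q_hat - Q(k)) / (k + 1)` (and likewise for `R`), so
#' `Q(k+1)` is exactly the cumulative average of the initial value and the
#' subsequent estimates. `P_prev` must be the covariance *before* the step
#' that produced `d`.
#'
#' @param state A `kalman_state` that has just completed [kf_step()].
#' @param p_prev Error covariance before the step.
#' @return The state with updated `Q`, `R` and fields `q_hat`, `r_hat`.
#' @export
adapt_qr <- function(state, p_prev) {
  if (!is.finite(state$K)) return(state) # nothing to adapt at init
  r_hat <- max(state$d^2 - p_prev, state$r_floor)
  q_hat <- max(state$K^2 * state$d^2, state$q_floor)
  w <- 1 / (state$k + 1)
  state$Q <- max(state$Q + w * (q_hat - state$Q), state$q_floor)
  state$R <- max(state$R + w * (r_hat - state$R), state$r_floor)
  state$q_hat <- q_hat
  state$r_hat <- r_hat
  state
}

#' Smooth a multi-DOF angle stream
#'
#' Runs one independent scalar adaptive Kalman filter per DOF column over
#' the whole series and returns the smoothed stream together with the full
#' per-iteration adaptation trace (for convergence plots of `Q` and `R`).
#'
#' @param angles Tibble with `time` and `dof*` columns (the regressor's raw
#'   output), or a numeric matrix/vector.
#' @param q_init,r_init,q_floor,r_floor,adapt Passed to [kalman_init()].
#' @return Tibble like `angles` with smoothed values and attribute
#'   `trace`: tibble (`dof`, `k`, `Q`, `R`, `q_hat`, `r_hat`), retrievable
#'   with [kalman_trace()].
#' @export
kalman_smooth <- function(angles, q_init = 0.05, r_init = 0.4,
                          q_floor = 1e-6, r_floor = 1e-4, adapt = TRUE) {
  is_df <- is.data.frame(angles)
  if (is_df) {
    dofs <- grep("^dof[0-9]+$", names(angles), value = TRUE)
    mat <- as.matrix(angles[, dofs, drop = FALSE])
  } else {
    mat <- as.matrix(angles)
    dofs <- colnames(mat) %||% paste0("dof", seq_len(ncol(mat)))
  }
  out <- mat
  traces <- vector("list", ncol(mat))
  for (j in seq_len(ncol(mat))) {
    st <- kalman_init(q_init, r_init, q_floor, r_floor, adapt)
    n <- nrow(mat)
    tr_k <- integer(n); tr_q <- tr_r <- tr_qh <- tr_rh <- numeric(n)
    for (i in seq_len(n)) {
      p_prev <- st$P
      stepped <- kf_step(st, mat[i, j])
      st <- stepped$state
      if (st$adapt) st <- adapt_qr(st, p_prev)
      out[i, j] <- stepped$x
      tr_k[i] <- st$k
      tr_q[i] <- st$Q; tr_r[i] <- st$R
      tr_qh[i] <- st$q_hat %||% NA_real_
      tr_rh[i] <- st$r_hat %||% NA_real_
    }
    traces[[j]] <- tibble(
      dof = dofs[j], k = tr_k, Q = tr_q, R = tr_r,
      q_hat = tr_qh, r_hat = tr_rh
    )
  }
  if (is_df) {
    res <- angles
    res[, dofs] <- as_tibble(out, .name_repair = "minimal")
  } else {
    res <- out
  }
  attr(res, "trace") <- dplyr::bind_rows(traces)
  res
}

#' Extract the Q/R adaptation trace from a smoothed stream
#'
#' @param smoothed Result of [kalman_smooth()].
#' @return Tibble (`dof`, `k`, `Q`, `R`, `q_hat`, `r_hat`).
#' @export
kalman_trace <- function(smoothed) {
  tr <- attr(smoothed, "trace")
  if (is.null(tr)) abort("No adaptation trace attached to this object.")
  tr
}

#' Steady-state error covariance of the non-adaptive filter
#'
#' With fixed `Q` and `R` the covariance recursion
#' `P <- (1 - P/(P+R)) P + Q` has the positive fixed point
#' `(Q + sqrt(Q^2 + 4QR)) / 2`, the closed-form root of
#' `P^2 - QP - QR = 0`. Useful as an analytic cross-check of the
#' iteration.
#'
#' @param q,r Fixed covariances.
#' @return The fixed-point covariance.
#' @export
kalman_p_fixed_point <- function(q = 0.05, r = 0.4) {
  (q + sqrt(q^2 + 4 * q * r)) / 2
}
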