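#' Pearson correlation coefficient
#'
#' Computed as the mean product of (N-1)-standardized scores,
#' `CC = 1/(N-1) * sum((X - mean(X))/sd(X) * (Y - mean(Y))/sd(Y))`,
#' with sample (N-1) standard deviations. The decoding accuracy metric:
#' 1 is perfect positive tracking, 0 no relationship.
#'
#' @param x,y Equal-length numeric series, `N >= 2`, non-constant.
#' @return The correlation, clamped to `[-1, 1]` against rounding.
#' @export
#' @examples
#' pearson_cc(c(1, 2, 3), c(1, 3, 2)) # 0.5
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) abort("Series must have equal length.")
  n <- length(x)
  if (n < 2) abort("Need at least 2 points.")
  sx <- sd(x)
  sy <- sd(y)
  if (sx == 0 || sy == 0) {
    abort("Undefined correlation: a series has zero variance.")
  }
  cc <- sum((x - mean(x)) / sx * (y - mean(y)) / sy) / (n - 1)
  min(max(cc, -1), 1)
}

#' Score a decoding session against measured angles
#'
#' Aligns the measured (motion-capture) angle stream onto the prediction
#' timestamps by linear interpolation, then reports the Pearson CC per DOF
#' over the whole session, and per motion class (single M1-M5, double
#' M6-M9, triple M10-M13, and all non-rest motions) over the concatenated
#' class segments of the driving script. A class's CC is the mean of its
#' three per-DOF correlations; a DOF that is constant within a class
#' segment (never recruited) is skipped.
#'
#' @param predicted Tibble `time`, `dof1..3` (e.g. `run_session()$angles`).
#' @param measured Tibble `time`, `dof1..3` at any rate.
#' @param script Optional `motion_script` that generated the session (may
#'   span several concatenated trials via a list); enables per-class CCs.
#' @return Tibble with columns `scope` (`"dof"` / `"class"`), `level`, `cc`
#'   and `n` (samples scored).
#' @export
score_session <- function(predicted, measured, script = NULL) {
  if (max(measured$time) < min(predicted$time) ||
      min(measured$time) > max(predicted$time)) {
    abort("Predicted and measured streams do not overlap in time.")
  }
  dofs <- intersect(c("dof1", "dof2", "dof3"), names(predicted))
  truth <- vapply(
    dofs,
    function(d) {
      approx(measured$time, measured[[d]], xout = predicted$time, rule = 2)$y
    },
    numeric(nrow(predicted))
  )
  rows <- lapply(dofs, function(d) {
    tibble(scope = "dof", level = d,
           cc = pearson_cc(predicted[[d]], truth[, d]),
           n = nrow(predicted))
  })
  if (!is.null(script)) {
    seg <- script_segments(script)
    cls_tbl <- motion_catalogue()[, c("motion", "class")]
    seg$class <- cls_tbl$class[match(seg$motion, cls_tbl$motion)]
    for (cl in c("single", "double", "triple", "all")) {
      keep_seg <- if (cl == "all") seg[seg$class != "rest", ] else {
        seg[seg$class == cl, ]
      }
      if (nrow(keep_seg) == 0) next
      in_class <- rep(FALSE, nrow(predicted))
      for (i in seq_len(nrow(keep_seg))) {
        in_class <- in_class |
          (predicted$time >= keep_seg$t_start[i] &
             predicted$time < keep_seg$t_end[i])
      }
      if (sum(in_class) < 3) next
      ccs <- vapply(seq_along(dofs), function(j) {
        p <- predicted[[dofs[j]]][in_class]
        t <- truth[in_class, j]
        if (sd(t) == 0 || sd(p) == 0) NA_real_ else pearson_cc(p, t)
      }, numeric(1))
      rows[[length(rows) + 1]] <- tibble(
        scope = "class", level = cl,
        cc = mean(ccs, na.rm = TRUE), n = sum(in_class)
      )
    }
  }
  dplyr::bind_rows(rows)
}

# absolute-time segment table for a script or list of scripts laid
# end to end (as simulate_session() concatenates trials)
script_segments <- function(script) {
  scripts <- if (inherits(script, "motion_script")) list(script) else script
  offset <- 0
  out <- list()
  for (s in scripts) {
    seg <- as_tibble(s)[, c("motion", "t_start", "t_end")]
    seg$t_start <- seg$t_start + offset
    seg$t_end <- seg$t_end + offset
    offset <- offset + max(s$t_end)
    out[[length(out) + 1]] <- seg
  }
  dplyr::bind_rows(out)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition: `F = MS_between / MS_within`
#' with `p` from the F distribution. Used to check that computational
#' latency does not drift across minutes of a session — following the
#' convention that the system is declared stable when `p > 0.5` (a
#' deliberately strict no-difference threshold, not the usual 0.05).
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values),
#'   or a data frame plus `value`/`group` column names.
#' @param value,group Column names when `groups` is a data frame.
#' @return One-row tibble: `f`, `p`, `df_between`, `df_within`,
#'   `n_groups`, plus list-columns `means` and `vars`.
#' @export
one_way_anova <- function(groups, value = "value", group = "group") {
  if (is.data.frame(groups)) {
    groups <- split(groups[[value]], groups[[group]])
  }
  k <- length(groups)
  if (k < 2) abort("Need at least two groups.")
  sizes <- lengths(groups)
  if (any(sizes < 2)) abort("Every group needs at least two values.")
  n <- sum(sizes)
  gm <- vapply(groups, mean, numeric(1))
  grand <- sum(sizes * gm) / n
  ss_between <- sum(sizes * (gm - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df_b <- k - 1
  df_w <- n - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  if (ms_w == 0) abort("Zero within-group variance: F undefined.")
  f <- ms_b / ms_w
  tibble(
    f = f, p = pf(f, df_b, df_w, lower.tail = FALSE),
    df_between = df_b, df_within = df_w, n_groups = k,
    means = list(gm), vars = list(vapply(groups, var, numeric(1)))
  )
}

#' Latency-stability check over a session
#'
#' Splits a latency stream into consecutive one-minute groups and runs
#' [one_way_anova()]; `p > 0.5` indicates the computational latency did not
#' vary across the session.
#'
#' @param latency Tibble with `time` (s) and `duration_ms` (from
#'   [run_session()]).
#' @param minutes Number of one-minute groups (default 5).
#' @return The [one_way_anova()] tibble with an extra `stable` column
#'   (`p > 0.5`).
#' @export
latency_anova <- function(latency, minutes = 5) {
  t0 <- min(latency$time)
  grp <- floor((latency$time - t0) / 60) + 1
  keep <- grp <= minutes
  res <- one_way_anova(split(latency$duration_ms[keep], grp[keep]))
  res$stable <- res$p > 0.5
  res
}
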