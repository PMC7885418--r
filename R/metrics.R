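#' @title Fitts's-law performance metrics
#'
#' @description
#' The five session metrics: completion rate (CR, %), completion time
#' (CT, s, successes only), path efficiency (PE, %), overshoot (O, exits
#' per target) and throughput (T, bits/s, mean of target-wise ID/CT over
#' successes), with the index of difficulty `ID = log2(D/W + 1)` (D =
#' center distance, W = target diameter), the ID-vs-CT linear regression,
#' and Cohen's d effect sizes computable either from raw samples or from
#' printed per-session summary moments.
#'
#' @name performance_metrics
NULL

#' Index of difficulty
#'
#' @param D straight-line distance from the origin to the target center
#'   (pixels).
#' @param W target diameter (pixels).
#' @return `log2(D / W + 1)` in bits.
#' @export
index_of_difficulty <- function(D, W) {
  if (any(W <= 0)) stop("W must be positive")
  if (any(D < 0)) stop("D must be nonnegative")
  log2(D / W + 1)
}

#' Session metrics from trial logs
#'
#' CR is the percentage of successful trials; CT averages completion time
#' over successes only; PE averages the ratio of the optimal (straight
#' line) path to the traversed path over *all* attempted targets
#' (dwell-period motion included; a trial with zero traversed path
#' contributes 0, and the ratio is capped at 1 so that an aborted trial
#' that barely moved cannot exceed the straight-line optimum); O is the total count of boundary exits before dwell
#' completion divided by the number of targets; T averages target-wise
#' ID/CT over successes. With zero successes CT and T are NA.
#'
#' @param logs list of `trial_log` objects (one per target).
#' @return Object of class `metric_set`: list with `CR`, `CT`, `PE`, `O`,
#'   `T`, `n_targets`, `n_success`.
#' @export
session_metrics <- function(logs) {
  n <- length(logs)
  ok <- vapply(logs, function(l) l$outcome == "success", logical(1))
  ct <- vapply(logs, function(l) l$completion_time, numeric(1))
  pl <- vapply(logs, function(l) l$path_length, numeric(1))
  D <- vapply(logs, function(l) l$target$distance, numeric(1))
  id <- vapply(logs, function(l) l$target$id_bits, numeric(1))
  ov <- vapply(logs, function(l) l$overshoots, numeric(1))
  pe_ratio <- ifelse(pl > 0, pmin(D / pl, 1), 0)
  structure(list(
    CR = 100 * mean(ok),
    CT = if (any(ok)) mean(ct[ok]) else NA_real_,
    PE = 100 * mean(pe_ratio),
    O = sum(ov) / n,
    T = if (any(ok)) mean(id[ok] / ct[ok]) else NA_real_,
    n_targets = n, n_success = sum(ok)), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> CR %.1f%% | CT %.2f s | PE %.1f%% | O %.3f | T %.3f bits/s (%d/%d targets)\n",
              x$CR, x$CT, x$PE, x$O, x$T, x$n_success, x$n_targets))
  invisible(x)
}

#' ID-vs-CT linear regression
#'
#' Ordinary least squares of target-wise completion time on index of
#' difficulty; a high coefficient of determination supports the validity
#' of the target-acquisition test.
#'
#' @param id numeric vector of indices of difficulty (>= 3 distinct
#'   values required).
#' @param ct matching completion times.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
fitts_regression <- function(id, ct) {
  keep <- is.finite(id) & is.finite(ct)
  id <- id[keep]; ct <- ct[keep]
  if (length(unique(id)) < 3) stop("degenerate regression: need >= 3 distinct ID values")
  fit <- stats::lm(ct ~ id)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Per-group summary moments
#'
#' Container for printed summary statistics (mean, SD, n) used to
#' reconstruct effect sizes from reported tables.
#'
#' @param mean group mean.
#' @param sd group standard deviation (>= 0).
#' @param n group size (>= 2).
#' @return Object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  if (sd < 0 || n < 2) stop("invalid group summary")
  structure(list(mean = mean, sd = sd, n = n), class = "group_summary")
}

#' Pool two equal-n session summaries into one group
#'
#' Reconstructs the moments of the concatenated group: the mean is the
#' mean of session means, the variance is the mean of session variances
#' plus the (population) variance of the session means.
#'
#' @param a,b `group_summary` objects with equal `n`.
#' @return A `group_summary` for the concatenation.
#' @export
concat_sessions <- function(a, b) {
  if (a$n != b$n) stop("unequal session sizes are not supported")
  m <- (a$mean + b$mean) / 2
  v <- (a$sd^2 + b$sd^2) / 2 + ((a$mean - b$mean) / 2)^2
  group_summary(m, sqrt(v), 2L * a$n)
}

#' Cohen's d effect size
#'
#' `d = (mean_a - mean_b) / s_pooled` with the equal-n pooled SD
#' `s_pooled = sqrt((s_a^2 + s_b^2) / 2)`. Accepts raw sample vectors
#' (population SDs are used, so that e.g. `{0,2}` vs `{1,3}` gives exactly
#' -1) or [group_summary()] objects carrying printed summary moments.
#'
#' @param a,b numeric vectors or `group_summary` objects.
#' @return Signed effect size (antisymmetric in its arguments).
#' @export
cohens_d <- function(a, b) {
  as_sum <- function(x) {
    if (inherits(x, "group_summary")) x
    else group_summary(mean(x), sqrt(mean((x - mean(x))^2)), length(x))
  }
  a <- as_sum(a); b <- as_sum(b)
  sp <- sqrt((a$sd^2 + b$sd^2) / 2)
  if (sp == 0) stop("zero pooled variance")
  (a$mean - b$mean) / sp
}

#' Mean of a metric across two sessions
#'
#' @param day1,day7 `group_summary` objects (equal n) or scalars.
#' @return Arithmetic mean of the two session means.
#' @export
cross_session_mean <- function(day1, day7) {
  m <- function(x) if (inherits(x, "group_summary")) x$mean else x
  if (inherits(day1, "group_summary") && inherits(day7, "group_summary") &&
      day1$n != day7$n) stop("unequal session sizes are not supported")
  (m(day1) + m(day7)) / 2
}
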