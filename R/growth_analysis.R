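# Colony growth mathematics: total-area series, log-linear regression,
# sliding-window maximal growth rate, initial growth rate, adaptation
# time from the fit intersection, normalization, time-weighted baseline
# and Monod goodness-of-fit.

#' Total colony area per frame
#'
#' Sums the cell areas of a pooled condition table per phase-contrast
#' frame.  The natural log of this series is the curve all growth-rate
#' fits operate on.
#'
#' @param table A pooled `cell_table`.
#' @return A data frame of class `growth_series` with columns `time_h`,
#'   `total_area` (square micrometres) and `cell_count`, sorted by time.
#' @export
growth_series <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) > 0,
            all(c("time_h", "area_um2") %in% names(table)))
  tot <- tapply(table$area_um2, table$time_h, sum)
  cnt <- tapply(table$area_um2, table$time_h, length)
  out <- data.frame(time_h = as.numeric(names(tot)),
                    total_area = as.numeric(tot),
                    cell_count = as.integer(cnt))
  out <- out[order(out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("growth_series", "data.frame")
  attr(out, "condition_key") <- attr(table, "condition_key")
  out
}

growth_fit <- function(slope, intercept, window, r_squared, n_points) {
  structure(list(slope = slope, intercept = intercept, window = window,
                 r_squared = r_squared, n_points = n_points),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit> mu = %.4f 1/h over [%.2f, %.2f) h (n = %d, R^2 = %.4f)\n",
    x$slope, x$window[1], x$window[2], x$n_points, x$r_squared))
  invisible(x)
}

#' Log-linear growth-rate fit over a time window
#'
#' Ordinary least squares of `ln(total_area)` (natural log, so the slope
#' is the specific growth rate in 1/h) against time over the frames in
#' the closed-open window `[t_start, t_end)`.
#'
#' @param series A [growth_series()].
#' @param window `c(t_start, t_end)` in hours.
#' @param response `"area"` (canonical) or `"count"` (cell-count based
#'   diagnostic).
#' @return A `growth_fit`: `slope` (1/h), `intercept` (ln area at t =
#'   0), `window`, `r_squared`, `n_points`.  Fewer than 3 frames in the
#'   window is an error.
#' @export
fit_log_linear <- function(series, window, response = c("area", "count")) {
  stopifnot(inherits(series, "growth_series") || is.data.frame(series),
            length(window) == 2, window[2] > window[1])
  response <- match.arg(response)
  sel <- series$time_h >= window[1] - 1e-9 & series$time_h < window[2] - 1e-9
  n <- sum(sel)
  if (n < 3)
    stop(sprintf(
      "insufficient data: %d frame(s) in window [%g, %g) h, need >= 3",
      n, window[1], window[2]), call. = FALSE)
  x <- series$time_h[sel]
  y <- log(if (response == "area") series$total_area[sel]
           else series$cell_count[sel])
  mx <- mean(x); my <- mean(y)
  dx <- x - mx
  sxx <- sum(dx^2)
  slope <- sum(dx * (y - my)) / sxx
  intercept <- my - slope * mx
  rss <- sum((y - intercept - slope * x)^2)
  tss <- sum((y - my)^2)
  r2 <- if (tss < 1e-12) (if (rss < 1e-12) 1 else 0)
        else min(max(1 - rss / tss, 0), 1)
  growth_fit(slope, intercept, c(window[1], window[2]), r2, n)
}

#' Maximal specific growth rate from a sliding window
#'
#' Evaluates [fit_log_linear()] on every complete window `[t, t +
#' window_h)` whose start frame lies at or after the onset of the
#' dynamics, advancing the window frame by frame, and returns the fit
#' with the maximal slope (ties broken by the earliest window).
#'
#' @param series A [growth_series()] extending at least `window_h` past
#'   `t_onset`.
#' @param t_onset Onset of the dynamics, h.
#' @param window_h Window length, h (default 3).
#' @param frame_step Advance between evaluated windows, frames
#'   (default 1).
#' @param response Passed to [fit_log_linear()].
#' @return The maximal-slope `growth_fit`.
#' @export
mu_max_sliding <- function(series, t_onset, window_h = 3, frame_step = 1,
                           response = "area") {
  times <- series$time_h
  t_max <- max(times)
  starts <- times[times >= t_onset - 1e-9 & times + window_h <= t_max + 1e-9]
  if (length(starts))
    starts <- starts[seq(1, length(starts), by = frame_step)]
  if (!length(starts))
    stop("no complete window after onset: series too short", call. = FALSE)
  best <- NULL
  for (s in starts) {
    ft <- tryCatch(
      fit_log_linear(series, c(s, s + window_h), response = response),
      error = function(e) NULL)
    if (!is.null(ft) && (is.null(best) || ft$slope > best$slope))
      best <- ft
  }
  if (is.null(best))
    stop("no window held enough frames for a fit", call. = FALSE)
  best
}

#' Initial growth rate after the onset of the dynamics
#'
#' Single fixed-window fit over the first `window_h` hours after onset
#' (default 1 h; at the 8-min phase-contrast cadence this holds 7-8
#' frames).
#'
#' @inheritParams mu_max_sliding
#' @param window_h Window length, h (default 1).
#' @return A `growth_fit`.
#' @export
mu_ini <- function(series, t_onset, window_h = 1, response = "area") {
  fit_log_linear(series, c(t_onset, t_onset + window_h), response = response)
}

#' Adaptation time from the intersection of the two growth fits
#'
#' The adaptation duration is the time from the onset of the dynamics to
#' the intersection of the initial-rate regression line and the
#' maximal-rate regression line.  It is reported only when a genuine
#' adaptation phase exists: `mu_ini < mu_max` and `mu_ini / mu_max <
#' 0.9` (the gate).  When the gate fails -- including slopes equal
#' within tolerance or an intersection before onset -- the duration is
#' reported as 0 with `gate_passed = FALSE`, keeping sweep tables
#' rectangular.
#'
#' @param fit_ini `growth_fit` from [mu_ini()].
#' @param fit_max `growth_fit` from [mu_max_sliding()].
#' @param t_onset Onset of the dynamics, h.
#' @param gate_ratio Gate threshold on `mu_ini / mu_max` (default 0.9).
#' @param slope_tol Minimal slope difference treated as distinct, 1/h.
#' @return An object of class `adaptation_result`: `mu_ini`, `mu_max`
#'   (1/h), `t_adapt` (h after onset), `mu_ratio`, `gate_passed`.
#' @export
adaptation_time <- function(fit_ini, fit_max, t_onset, gate_ratio = 0.9,
                            slope_tol = 1e-9) {
  stopifnot(inherits(fit_ini, "growth_fit"), inherits(fit_max, "growth_fit"))
  mu_i <- fit_ini$slope
  mu_m <- fit_max$slope
  ratio <- if (abs(mu_m) > slope_tol) mu_i / mu_m else NA_real_
  gate <- is.finite(ratio) && mu_i < mu_m && ratio < gate_ratio &&
    (mu_m - mu_i) > slope_tol
  t_ad <- 0
  if (gate) {
    t_star <- (fit_ini$intercept - fit_max$intercept) / (mu_m - mu_i)
    t_ad <- t_star - t_onset
    if (t_ad < 0) {
      gate <- FALSE
      t_ad <- 0
    }
  }
  structure(list(mu_ini = mu_i, mu_max = mu_m, t_adapt = t_ad,
                 mu_ratio = ratio, gate_passed = gate),
            class = "adaptation_result")
}

#' @export
print.adaptation_result <- function(x, ...) {
  cat(sprintf(
    "<adaptation_result> mu_ini = %.4f, mu_max = %.4f 1/h (ratio %.3f); t_adapt = %.3f h%s\n",
    x$mu_ini, x$mu_max, x$mu_ratio, x$t_adapt,
    if (x$gate_passed) "" else " [gate failed]"))
  invisible(x)
}

#' Normalize a growth rate to the excess control of the same experiment
#'
#' @param mu Growth rate, 1/h.
#' @param mu_excess_control Maximal growth rate of the constant-excess
#'   control, 1/h (> 0).
#' @return Dimensionless ratio; the control normalizes to exactly 1.
#' @export
normalize_mu <- function(mu, mu_excess_control) {
  if (!is.numeric(mu_excess_control) || mu_excess_control <= 0)
    stop("'mu_excess_control' must be positive", call. = FALSE)
  mu / mu_excess_control
}

#' Time-weighted-average growth baseline
#'
#' The growth rate expected if the colony simply averaged its two
#' constant-condition rates over the duty cycle: `f * mu_excess + (1 -
#' f) * mu_limitation`.  Measured adapted rates exceeding this baseline
#' indicate physiology beyond concentration averaging.
#'
#' @param mu_excess_ctrl,mu_limitation_ctrl Constant-condition growth
#'   rates, 1/h.
#' @param profile The condition's [make_profile()].
#' @return Baseline growth rate, 1/h.
#' @export
time_weighted_mu <- function(mu_excess_ctrl, mu_limitation_ctrl, profile) {
  f <- duty_cycle(profile)
  f * mu_excess_ctrl + (1 - f) * mu_limitation_ctrl
}

#' Duty-cycle-weighted mean glucose concentration
#'
#' The substrate covariate used for the Monod fit: `f * c_excess + (1 -
#' f) * c_limitation`.
#'
#' @param profile An [make_profile()].
#' @return Concentration, g/L.
#' @export
effective_substrate <- function(profile) {
  f <- duty_cycle(profile)
  f * profile$c_excess + (1 - f) * profile$c_limitation
}

#' Monod fit of growth rate against effective glucose concentration
#'
#' Nonlinear least squares of `mu = mu_m * S / (Ks + S)`
#' (Levenberg-Marquardt).  Used to test whether a concentration-only
#' model explains the dose-response of growth under oscillating glucose
#' -- for the dMSCC data it does not, which shows up as R-squared well
#' below 1.
#'
#' @param S Effective substrate concentrations, g/L (at least 3 distinct
#'   values).
#' @param mu Growth rates, 1/h.
#' @return A list: `mu_m` (1/h), `Ks` (g/L), `r_squared`, `converged`,
#'   and the underlying `fit` object when converged.
#' @export
fit_monod <- function(S, mu) {
  stopifnot(is.numeric(S), is.numeric(mu), length(S) == length(mu))
  if (length(unique(S)) < 3)
    stop("need at least 3 distinct substrate concentrations", call. = FALSE)
  df <- data.frame(S = S, mu = mu)
  start <- list(mu_m = max(mu), Ks = max(stats::median(S), 1e-3))
  fit <- tryCatch(
    minpack.lm::nlsLM(mu ~ mu_m * S / (Ks + S), data = df, start = start,
                      lower = c(mu_m = 0, Ks = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(list(mu_m = NA_real_, Ks = NA_real_, r_squared = NA_real_,
                converged = FALSE, message = conditionMessage(fit)))
  est <- stats::coef(fit)
  pred <- stats::predict(fit)
  tss <- sum((mu - mean(mu))^2)
  rss <- sum((mu - pred)^2)
  r2 <- if (tss < 1e-15) NA_real_ else 1 - rss / tss
  list(mu_m = unname(est[["mu_m"]]), Ks = unname(est[["Ks"]]),
       r_squared = r2, converged = TRUE, fit = fit)
}
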