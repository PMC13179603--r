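# Oscillating glucose environment, chip geometry, per-array time shifts,
# along-array pulse smoothing, and pulse-fidelity estimation.

#' Square-wave glucose oscillation profile
#'
#' Constructs the environmental forcing applied to on-chip cultivation
#' chambers: a fixed-period square wave alternating between a glucose
#' excess phase and a glucose limitation phase.  Each period begins with
#' the excess phase (cells enter the dynamics from a pre-phase under
#' constant excess, so an excess-first convention avoids a step
#' discontinuity at onset).
#'
#' @param excess_s Duration of the excess phase within one period, seconds.
#' @param limitation_s Duration of the limitation phase, seconds.  Must
#'   satisfy `excess_s + limitation_s == period_s`.
#' @param period_s Oscillation period, seconds (default 30).
#' @param c_excess Glucose concentration during excess, g/L (default 50).
#' @param c_limitation Glucose concentration during limitation, g/L
#'   (default 0.01, i.e. 10 mg/L).
#' @param phase_shift_s Temporal shift of the wave, seconds; 0 for the
#'   central arrays, set by [shift_profile()] for peripheral arrays.
#'
#' @return An object of class `osc_profile` with fields `period_s`,
#'   `excess_s`, `limitation_s`, `c_excess`, `c_limitation`,
#'   `phase_shift_s`, a derived `role` (`"dynamic"`, `"excess_control"`
#'   for duty cycle 1, `"limitation_control"` for duty cycle 0) and an
#'   `array_index` slot (filled by [shift_profile()]).
#' @seealso [glucose_at()], [shift_profile()], [duty_cycle()]
#' @export
#' @examples
#' p <- make_profile(3, 27)
#' duty_cycle(p)  # 0.1
make_profile <- function(excess_s, limitation_s, period_s = 30,
                         c_excess = 50, c_limitation = 0.01,
                         phase_shift_s = 0) {
  if (!is.numeric(excess_s) || length(excess_s) != 1L || is.na(excess_s) ||
      excess_s < 0)
    stop("'excess_s' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(limitation_s) || length(limitation_s) != 1L ||
      is.na(limitation_s) || limitation_s < 0)
    stop("'limitation_s' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(period_s) || length(period_s) != 1L || period_s <= 0)
    stop("'period_s' must be a single positive number", call. = FALSE)
  if (abs(excess_s + limitation_s - period_s) > 1e-9)
    stop(sprintf(
      "'excess_s' (%g) + 'limitation_s' (%g) must equal 'period_s' (%g)",
      excess_s, limitation_s, period_s), call. = FALSE)
  if (c_limitation < 0)
    stop("'c_limitation' must be non-negative", call. = FALSE)
  if (c_excess <= c_limitation)
    stop("'c_excess' must exceed 'c_limitation'", call. = FALSE)

  role <- if (excess_s >= period_s - 1e-12) "excess_control"
          else if (excess_s <= 1e-12) "limitation_control"
          else "dynamic"
  structure(
    list(period_s = period_s, excess_s = excess_s, limitation_s = limitation_s,
         c_excess = c_excess, c_limitation = c_limitation,
         phase_shift_s = phase_shift_s, role = role,
         array_index = NA_integer_),
    class = "osc_profile")
}

#' @export
print.osc_profile <- function(x, ...) {
  cat(sprintf(
    "<osc_profile> %g s period: %g s excess (%.0f g/L) / %g s limitation (%g g/L)\n",
    x$period_s, x$excess_s, x$c_excess, x$limitation_s, x$c_limitation))
  cat(sprintf("  duty cycle %.3f, phase shift %g s, role '%s'\n",
              duty_cycle(x), x$phase_shift_s, x$role))
  invisible(x)
}

#' Fraction of each oscillation period spent at glucose excess
#'
#' @param profile An [make_profile()] object.
#' @return Duty cycle `excess_s / period_s`, in `[0, 1]`.
#' @export
duty_cycle <- function(profile) {
  stopifnot(inherits(profile, "osc_profile"))
  profile$excess_s / profile$period_s
}

#' Glucose concentration seen by a chamber at a given time
#'
#' Before `onset` the chip is held at constant excess (the pre-phase of
#' the cultivation); afterwards the square wave runs with the profile's
#' phase shift, excess phase first.
#'
#' @param profile An [make_profile()] object.
#' @param t Time(s), seconds; vectorized.
#' @param onset Time at which the oscillation starts, seconds.
#' @return Numeric vector of concentrations, g/L.
#' @export
glucose_at <- function(profile, t, onset = 0) {
  stopifnot(inherits(profile, "osc_profile"), is.numeric(t))
  out <- rep(profile$c_excess, length(t))
  post <- !is.na(t) & t >= onset
  if (any(post)) {
    tau <- (t[post] - onset - profile$phase_shift_s) %% profile$period_s
    out[post] <- ifelse(tau < profile$excess_s - 1e-12,
                        profile$c_excess, profile$c_limitation)
  }
  out
}

#' Chip geometry of the cultivation device
#'
#' @param n_arrays Number of parallel cultivation arrays (odd; default 7;
#'   a central array flanked symmetrically).
#' @param chambers_per_array Monolayer growth chambers per array
#'   (default 27).
#' @param chamber_dims Chamber width, height, depth in micrometres
#'   (default `c(80, 90, 4)`).
#' @param array_shift_step_s Phase shift accumulated per array step away
#'   from the chip centre, seconds (default 2).
#' @return An object of class `chip_layout`.
#' @export
chip_layout <- function(n_arrays = 7, chambers_per_array = 27,
                        chamber_dims = c(80, 90, 4),
                        array_shift_step_s = 2) {
  if (n_arrays < 1 || n_arrays %% 2 != 1)
    stop("'n_arrays' must be odd (a centre flanked symmetrically)",
         call. = FALSE)
  if (chambers_per_array < 1)
    stop("'chambers_per_array' must be >= 1", call. = FALSE)
  stopifnot(length(chamber_dims) == 3, all(chamber_dims > 0))
  structure(
    list(n_arrays = n_arrays, chambers_per_array = chambers_per_array,
         chamber_dims = chamber_dims,
         array_shift_step_s = array_shift_step_s),
    class = "chip_layout")
}

#' Oscillation profile experienced by a given array
#'
#' The laminar flow boundary takes a few seconds to traverse the chip
#' width, so each array step away from the centre delays the wave by
#' `array_shift_step_s` and transfers the same amount of time from one
#' phase to the other (the left side lengthens the excess phase, the
#' right side shortens it).  The outermost arrays never see the
#' oscillation: they are held at constant conditions and serve as the
#' excess (array 1) and limitation (array `n_arrays`) controls.
#'
#' @param profile Nominal profile at the chip centre.
#' @param layout A [chip_layout()].
#' @param array_index 1-based array index, 1 = leftmost.
#' @return An `osc_profile` with adjusted `phase_shift_s`, distorted
#'   phase durations, and `array_index` recorded; constant-condition
#'   control profiles for the outermost arrays.
#' @export
shift_profile <- function(profile, layout = chip_layout(), array_index) {
  stopifnot(inherits(profile, "osc_profile"), inherits(layout, "chip_layout"))
  n <- layout$n_arrays
  if (!is.numeric(array_index) || length(array_index) != 1L ||
      array_index < 1 || array_index > n)
    stop(sprintf("'array_index' must be in 1..%d", n), call. = FALSE)
  p <- profile$period_s
  if (array_index == 1) {
    out <- make_profile(p, 0, p, profile$c_excess, profile$c_limitation)
  } else if (array_index == n) {
    out <- make_profile(0, p, p, profile$c_excess, profile$c_limitation)
  } else {
    centre <- (n + 1) / 2
    d <- array_index - centre
    step <- layout$array_shift_step_s
    excess_new <- min(max(profile$excess_s - d * step, 0), p)
    out <- make_profile(excess_new, p - excess_new, p,
                        profile$c_excess, profile$c_limitation,
                        phase_shift_s = profile$phase_shift_s + d * step)
  }
  out$array_index <- as.integer(array_index)
  out
}

#' Concentration trace inside a cultivation chamber
#'
#' Build a `chamber_trace` object from raw vectors (e.g. a dye
#' measurement) or see [chamber_response()] for the model-generated
#' version.
#'
#' @param times Strictly increasing, uniformly spaced times, seconds.
#' @param concentration Concentration (or dye fluorescence) values.
#' @param array_index,chamber_index 1-based chip coordinates
#'   (chamber 1 is nearest the inlet).
#' @param profile Optional nominal [make_profile()] driving the trace.
#' @return An object of class `chamber_trace`.
#' @export
chamber_trace <- function(times, concentration, array_index = NA_integer_,
                          chamber_index = NA_integer_, profile = NULL) {
  stopifnot(is.numeric(times), is.numeric(concentration),
            length(times) == length(concentration), length(times) >= 2)
  dt <- diff(times)
  if (any(dt <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("'times' must be a uniform grid", call. = FALSE)
  structure(
    list(times = times, concentration = concentration,
         array_index = as.integer(array_index),
         chamber_index = as.integer(chamber_index), profile = profile),
    class = "chamber_trace")
}

#' First-order washout model of a chamber's response to the channel wave
#'
#' Medium exchange between the supply channel and a chamber is modelled
#' as a linear first-order relaxation, `dC/dt = k(n) (C_channel(t) - C)`,
#' with an exchange rate that decays geometrically along the array,
#' `k(n) = k0 * decay^(n - 1)`: the first chambers exchange fast while a
#' laminar layer carrying former chamber contents reduces the diffusion
#' gradient further down the array, smoothing the oscillation.  The trace
#' starts at the exact periodic steady state, and one further burn-in
#' period is simulated and discarded, so its time-average equals the
#' duty-cycle-weighted mean of the driving wave.
#'
#' @param profile Driving [make_profile()] (phase shift honoured).
#' @param chamber_index 1-based chamber position along the array.
#' @param k0 Exchange rate of chamber 1, 1/s; must be positive.
#' @param decay Geometric decay of the exchange rate per chamber,
#'   in (0, 1].
#' @param dt Output sampling step, seconds (<= 0.5).
#' @param n_periods Number of periods covered by the returned trace.
#' @return A [chamber_trace()] covering `[0, n_periods * period_s]`.
#' @export
chamber_response <- function(profile, chamber_index = 1, k0 = 1, decay = 0.9,
                             dt = 0.1, n_periods = 6) {
  stopifnot(inherits(profile, "osc_profile"))
  if (k0 <= 0) stop("'k0' must be positive", call. = FALSE)
  if (decay <= 0 || decay > 1)
    stop("'decay' must be in (0, 1]", call. = FALSE)
  if (dt > 0.5) stop("'dt' must be <= 0.5 s", call. = FALSE)
  if (chamber_index < 1) stop("'chamber_index' must be >= 1", call. = FALSE)

  p <- profile$period_s
  y <- profile$excess_s
  x <- profile$limitation_s
  ce <- profile$c_excess
  cl <- profile$c_limitation
  k <- k0 * decay^(chamber_index - 1)
  times <- seq(0, n_periods * p, by = dt)

  if (y <= 1e-12 || x <= 1e-12) {
    # constant driving condition: steady state is the constant itself
    const <- if (y <= 1e-12) cl else ce
    return(chamber_trace(times, rep(const, length(times)),
                         array_index = profile$array_index,
                         chamber_index = chamber_index, profile = profile))
  }

  # periodic steady state evaluated at the start of an excess phase
  Ey <- exp(-k * y)
  Ex <- exp(-k * x)
  den <- 1 - Ex * Ey
  C0 <- if (den < 1e-12) (cl * x + ce * y) / p
        else (cl * (1 - Ex) + ce * (1 - Ey) * Ex) / den

  # integrate segment-wise from an excess start one burn-in period before 0
  s0 <- profile$phase_shift_s %% p
  a0 <- s0 - p
  n_per <- n_periods + 2L
  starts <- a0 + as.vector(rbind(seq_len(n_per) - 1, seq_len(n_per) - 1)) * p +
    rep(c(0, y), n_per)
  inputs <- rep(c(ce, cl), n_per)

  conc <- rep(NA_real_, length(times))
  t_max <- max(times)
  Cs <- C0  # periodic steady state at an excess start
  for (i in seq_along(starts)) {
    a <- starts[i]
    b <- if (i < length(starts)) starts[i + 1] else t_max + dt
    cin <- inputs[i]
    sel <- times >= a - 1e-12 & times < b - 1e-12
    if (any(sel))
      conc[sel] <- cin + (Cs - cin) * exp(-k * (times[sel] - a))
    Cs <- cin + (Cs - cin) * exp(-k * (b - a))
    if (a > t_max) break
  }
  conc <- pmin(pmax(conc, cl), ce)
  chamber_trace(times, conc, array_index = profile$array_index,
                chamber_index = chamber_index, profile = profile)
}

#' Pulse fidelity metrics of a chamber trace
#'
#' Quantifies how faithfully a chamber reproduces the nominal square
#' wave, mirroring the dye-based chip characterization: per cycle the
#' effective excess and limitation durations are read off threshold
#' crossings at 50% of the *achieved* amplitude and averaged over
#' cycles; the onset shift is the mean lag of the upward crossings
#' relative to the nominal wave; `definition` is the achieved amplitude
#' divided by the nominal amplitude.
#'
#' @param trace A [chamber_trace()] spanning at least 3 full periods.
#' @param nominal The nominal, unshifted [make_profile()].
#' @return An object of class `pulse_metrics`: `effective_excess_s`,
#'   `effective_limitation_s`, `onset_shift_s`, `definition`, `n_cycles`.
#'   For traces that never cross the threshold (flat traces) the
#'   durations and onset shift are `NA` and only `definition` is
#'   meaningful.
#' @export
estimate_pulse_metrics <- function(trace, nominal) {
  stopifnot(inherits(trace, "chamber_trace"), inherits(nominal, "osc_profile"))
  p <- nominal$period_s
  if (diff(range(trace$times)) < 3 * p - 1e-9)
    stop("trace must span at least 3 full periods", call. = FALSE)
  v <- trace$concentration
  tt <- trace$times
  amp_nom <- nominal$c_excess - nominal$c_limitation
  amp <- max(v) - min(v)
  definition <- min(max(amp / amp_nom, 0), 1)

  empty <- structure(
    list(effective_excess_s = NA_real_, effective_limitation_s = NA_real_,
         onset_shift_s = NA_real_, definition = definition, n_cycles = 0L),
    class = "pulse_metrics")
  if (amp <= 1e-6 * amp_nom) return(empty)

  thr <- min(v) + amp / 2
  lo <- v[-length(v)]
  hi <- v[-1]
  up_i <- which(lo <= thr & hi > thr)
  dn_i <- which(lo > thr & hi <= thr)
  cross_t <- function(i) tt[i] + (thr - v[i]) / (v[i + 1] - v[i]) *
    (tt[i + 1] - tt[i])
  t_up <- vapply(up_i, cross_t, numeric(1))
  t_dn <- vapply(dn_i, cross_t, numeric(1))
  if (length(t_up) < 2 || length(t_dn) < 2) return(empty)

  # excess duration: upward crossing to next downward crossing
  nxt <- function(from, pool) {
    out <- vapply(from, function(a) {
      cand <- pool[pool > a]
      if (length(cand)) cand[1] else NA_real_
    }, numeric(1))
    out - from
  }
  exc <- nxt(t_up, t_dn)
  lim <- nxt(t_dn, t_up)
  wrap <- function(z) ((z + p / 2) %% p) - p / 2
  structure(
    list(effective_excess_s = mean(exc, na.rm = TRUE),
         effective_limitation_s = mean(lim, na.rm = TRUE),
         onset_shift_s = mean(wrap(t_up - nominal$phase_shift_s)),
         definition = definition,
         n_cycles = sum(!is.na(exc))),
    class = "pulse_metrics")
}

#' @export
print.pulse_metrics <- function(x, ...) {
  cat(sprintf(
    "<pulse_metrics> excess %.2f s / limitation %.2f s, onset shift %+.2f s, definition %.3f (%d cycles)\n",
    x$effective_excess_s, x$effective_limitation_s, x$onset_shift_s,
    x$definition, x$n_cycles))
  invisible(x)
}

#' Write / read a chamber trace as CSV with a JSON sidecar
#'
#' The CSV holds two columns (`time_s`, `value`); the sidecar
#' `<path>.json` records the chip coordinates and the nominal profile.
#'
#' @param trace A [chamber_trace()].
#' @param path CSV output path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns
#'   a [chamber_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "chamber_trace"))
  utils::write.csv(
    data.frame(time_s = trace$times, value = trace$concentration),
    path, row.names = FALSE)
  side <- list(array_index = trace$array_index,
               chamber_index = trace$chamber_index)
  if (!is.null(trace$profile))
    side$profile <- trace$profile[c("period_s", "excess_s", "limitation_s",
                                    "c_excess", "c_limitation",
                                    "phase_shift_s")]
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("trace CSV must have columns 'time_s' and 'value'", call. = FALSE)
  side_path <- paste0(path, ".json")
  ai <- NA_integer_; ci <- NA_integer_; prof <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    ai <- side$array_index %||% NA_integer_
    ci <- side$chamber_index %||% NA_integer_
    if (!is.null(side$profile))
      prof <- do.call(make_profile, side$profile[c(
        "excess_s", "limitation_s", "period_s", "c_excess", "c_limitation",
        "phase_shift_s")])
  }
  chamber_trace(df$time_s, df$value, array_index = ai, chamber_index = ci,
                profile = prof)
}
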