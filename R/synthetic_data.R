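# Agent-based generator of synthetic dMSCC single-cell tables: budding
# colonies under square-wave glucose oscillations, with two-phase growth
# adaptation, ratiometric sensor readouts and condition-dependent sizes.

#' Fraction of the oscillation period spent at glucose excess
#'
#' The independent variable of all condition sweeps: `f = excess_s /
#' period_s`.
#'
#' @param profile An [make_profile()] object.
#' @return `f` in `[0, 1]`.
#' @export
#' @examples
#' effective_excess_fraction(make_profile(3, 27))  # 0.1
effective_excess_fraction <- function(profile) {
  duty_cycle(profile)
}

#' Strain parameterization for the synthetic-data generator
#'
#' Bundles a strain's growth rates, dose-response calibrations and noise
#' model.  All dose-response maps are functions of the excess fraction
#' `f` and equal 1 at `f = 1` (the excess control); all are monotone
#' non-decreasing except `dose_response_fbp`, which decreases with `f`
#' because the GlyRNA readout (CFP/RFP) falls as glycolytic flux rises.
#'
#' @param name Strain label.
#' @param mu_excess Adapted specific growth rate under constant excess,
#'   1/h.
#' @param mu_limitation Growth rate under constant limitation, 1/h.
#' @param dose_response_mu Function `f -> adapted mu / mu_excess`.
#' @param dose_response_atp Function `f -> normalized QUEEN-2m ratio`.
#' @param dose_response_fbp Function `f -> normalized GlyRNA ratio`
#'   (non-increasing).
#' @param dose_response_size Function `f -> normalized median area`
#'   for dynamic conditions.
#' @param mu_ini_fraction Function `f -> mu_ini / mu_adapted` in (0, 1].
#' @param t_adapt Function `f -> adaptation duration, h` (non-increasing).
#' @param division_area Budding threshold, square micrometres.
#' @param division_cv Coefficient of variation of the per-cell
#'   size-control jitter on the division threshold (redrawn at every
#'   division).  Desynchronizes lineages; never affects the total
#'   colony area, which divisions conserve.
#' @param bud_fraction Daughter share of area at division, in (0, 0.5).
#' @param size_limitation_control Size multiplier under the
#'   constant-limitation control (> 1: cells enlarge under constant
#'   limitation even though dynamic short-excess conditions shrink them).
#' @param atp_subpops Optional heritable ATP subpopulations:
#'   `list(fraction_high =, level_low =, level_high =)` multiplicative
#'   levels around the dose-response mean.
#' @param fbp_outliers Optional heritable high-GlyRNA outliers:
#'   `list(fraction =, level =)`.
#' @param noise_cv_area,noise_cv_fluor Coefficients of variation of the
#'   multiplicative lognormal measurement noise.
#' @param gray_scales Named numeric scale (arbitrary fluorescence units)
#'   of the four channels `rfp`, `gfp`, `cfp`, `uvgfp`.
#' @return An object of class `strain_params`.
#' @seealso [default_strain_params()]
#' @export
strain_params <- function(name, mu_excess, mu_limitation,
                          dose_response_mu, dose_response_atp,
                          dose_response_fbp, dose_response_size,
                          mu_ini_fraction, t_adapt,
                          division_area = 50, division_cv = 0.08,
                          bud_fraction = 0.35,
                          size_limitation_control = 1.12,
                          atp_subpops = NULL, fbp_outliers = NULL,
                          noise_cv_area = 0.04, noise_cv_fluor = 0.05,
                          gray_scales = c(rfp = 500, gfp = 400,
                                          cfp = 500, uvgfp = 320)) {
  stopifnot(mu_excess > 0, mu_limitation > 0, mu_limitation < mu_excess,
            division_area > 0)
  if (bud_fraction <= 0 || bud_fraction >= 0.5)
    stop("'bud_fraction' must be in (0, 0.5)", call. = FALSE)
  grid <- seq(0, 1, by = 0.02)
  chk <- function(fn, nm, decreasing = FALSE, at_one = TRUE) {
    v <- fn(grid)
    d <- diff(v)
    ok <- if (decreasing) all(d <= 1e-9) else all(d >= -1e-9)
    if (!ok) stop(sprintf("'%s' must be monotone %s in f", nm,
                          if (decreasing) "non-increasing" else
                            "non-decreasing"), call. = FALSE)
    if (at_one && abs(fn(1) - 1) > 1e-9)
      stop(sprintf("'%s' must equal 1 at f = 1", nm), call. = FALSE)
  }
  chk(dose_response_mu, "dose_response_mu")
  chk(dose_response_atp, "dose_response_atp")
  chk(dose_response_fbp, "dose_response_fbp", decreasing = TRUE)
  chk(dose_response_size, "dose_response_size")
  chk(mu_ini_fraction, "mu_ini_fraction")
  chk(t_adapt, "t_adapt", decreasing = TRUE, at_one = FALSE)
  structure(
    list(name = name, mu_excess = mu_excess, mu_limitation = mu_limitation,
         dose_response_mu = dose_response_mu,
         dose_response_atp = dose_response_atp,
         dose_response_fbp = dose_response_fbp,
         dose_response_size = dose_response_size,
         mu_ini_fraction = mu_ini_fraction, t_adapt = t_adapt,
         division_area = division_area, division_cv = division_cv,
         bud_fraction = bud_fraction,
         size_limitation_control = size_limitation_control,
         atp_subpops = atp_subpops, fbp_outliers = fbp_outliers,
         noise_cv_area = noise_cv_area, noise_cv_fluor = noise_cv_fluor,
         gray_scales = gray_scales),
    class = "strain_params")
}

#' Default calibrations for the three reference yeast strains
#'
#' Dose-response maps are shape-preserving monotone cubic interpolants
#' through the calibration anchors: all strains retain 50% of the
#' excess-control growth rate at `f = 0.1`; CEN.PK113-7D and PE2 hold
#' 90% of the maximal ATP level under constant limitation while Ethanol
#' Red holds only 70%; the GlyRNA readout rises by 40% from constant
#' excess to constant limitation identically for all strains; Ethanol
#' Red's median cell size falls to ~70% at the shortest excess phases
#' whereas the other two strains plateau near 90%.  Ethanol Red carries
#' two heritable ATP subpopulations; PE2 carries a small heritable
#' fraction of high-GlyRNA outlier cells.
#'
#' @param strain One of `"CEN.PK113-7D"`, `"Ethanol Red"`, `"PE2"`.
#' @return A [strain_params()] object.
#' @export
#' @examples
#' p <- default_strain_params("CEN.PK113-7D")
#' p$dose_response_mu(0.1)  # 0.5
default_strain_params <- function(strain = c("CEN.PK113-7D", "Ethanol Red",
                                             "PE2")) {
  strain <- match.arg(strain)
  f_mu <- c(0, 0.1, 0.3, 0.5, 0.7, 1)
  v_mu <- c(0.25, 0.5, 0.72, 0.85, 0.93, 1)
  f_fbp <- c(0, 0.25, 0.5, 0.75, 1)
  v_fbp <- c(1.4, 1.32, 1.2, 1.09, 1)
  f_ini <- c(0, 0.1, 0.3, 0.5, 0.7, 1)
  v_ini <- c(0.30, 0.40, 0.50, 0.70, 0.92, 1)
  f_sz2 <- c(0, 0.1, 0.3, 17 / 30, 1)        # CEN.PK / PE2 size plateau
  v_sz2 <- c(0.88, 0.90, 0.945, 1, 1)
  f_szE <- c(0, 0.1, 0.3, 0.5, 17 / 30, 0.75, 1)  # Ethanol Red
  v_szE <- c(0.68, 0.70, 0.80, 0.90, 0.92, 0.96, 1)
  f_ta <- c(0, 0.1, 0.3, 0.5, 0.7, 1)

  switch(strain,
    "CEN.PK113-7D" = strain_params(
      name = strain, mu_excess = 0.185, mu_limitation = 0.046,
      dose_response_mu = mono_map(f_mu, v_mu),
      dose_response_atp = mono_map(c(0, 0.5, 1), c(0.90, 0.95, 1)),
      dose_response_fbp = mono_map(f_fbp, v_fbp),
      dose_response_size = mono_map(f_sz2, v_sz2),
      mu_ini_fraction = mono_map(f_ini, v_ini),
      t_adapt = mono_map(f_ta, c(3.4, 3.2, 3.0, 2.5, 2.0, 0)),
      division_area = 50),
    "Ethanol Red" = strain_params(
      name = strain, mu_excess = 0.20, mu_limitation = 0.050,
      dose_response_mu = mono_map(f_mu, v_mu),
      dose_response_atp = mono_map(c(0, 0.5, 1), c(0.70, 0.85, 1)),
      dose_response_fbp = mono_map(f_fbp, v_fbp),
      dose_response_size = mono_map(f_szE, v_szE),
      mu_ini_fraction = mono_map(f_ini, v_ini),
      t_adapt = mono_map(f_ta, c(3.4, 3.2, 3.1, 2.5, 2.0, 0)),
      division_area = 52,
      atp_subpops = list(fraction_high = 0.6, level_low = 0.75,
                         level_high = 7 / 6)),
    "PE2" = strain_params(
      name = strain, mu_excess = 0.17, mu_limitation = 0.0425,
      dose_response_mu = mono_map(f_mu, v_mu),
      dose_response_atp = mono_map(c(0, 0.5, 1), c(0.90, 0.95, 1)),
      dose_response_fbp = mono_map(f_fbp, v_fbp),
      dose_response_size = mono_map(f_sz2, v_sz2),
      mu_ini_fraction = mono_map(f_ini, v_ini),
      t_adapt = mono_map(f_ta, c(3.6, 3.4, 3.2, 2.7, 2.1, 0)),
      division_area = 48,
      fbp_outliers = list(fraction = 0.03, level = 1.6)))
}

#' Simulation configuration
#'
#' @param seed Master integer seed; each chamber derives an independent
#'   stream from it, so per-chamber results do not depend on
#'   `n_chambers`.
#' @param profile Driving [make_profile()]; its `role` decides whether
#'   the run is a dynamic condition or a constant control.
#' @param n_chambers Number of chambers to simulate.  Chamber indices
#'   cycle through 1-10 (the analyzable chamber positions) across
#'   arrays.
#' @param cells_per_chamber_init Range `c(min, max)` of seeded cells per
#'   chamber (default 1-3).
#' @param t_end Cultivation end, h (default 18).
#' @param t_onset Onset of the dynamics after the pre-phase under
#'   constant excess, h (default 4).
#' @param dt_phase_min Phase-contrast imaging cadence, min (default 8).
#' @param dt_fluor_min Fluorescence imaging cadence, min (default 32;
#'   must be an integer multiple of `dt_phase_min`).
#' @param chamber_capacity_area Total colony area at which a chamber
#'   overflows and its record stream is truncated, square micrometres
#'   (default half the 80x90 chamber footprint).
#' @param condition_id Optional condition label; derived from the
#'   profile when `NULL`.
#' @param experiment_id Experiment label for provenance.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed, profile, n_chambers = 10,
                       cells_per_chamber_init = c(1, 3), t_end = 18,
                       t_onset = 4, dt_phase_min = 8, dt_fluor_min = 32,
                       chamber_capacity_area = 0.5 * 80 * 90,
                       condition_id = NULL, experiment_id = "sim") {
  stopifnot(inherits(profile, "osc_profile"), n_chambers >= 1,
            length(cells_per_chamber_init) == 2,
            cells_per_chamber_init[1] >= 1,
            cells_per_chamber_init[2] >= cells_per_chamber_init[1])
  if (t_onset >= t_end) stop("'t_onset' must be < 't_end'", call. = FALSE)
  if (dt_fluor_min %% dt_phase_min != 0)
    stop("'dt_fluor_min' must be an integer multiple of 'dt_phase_min'",
         call. = FALSE)
  if (is.null(condition_id))
    condition_id <- sprintf("e%02.0fs_%s", profile$excess_s,
                            sub("_control", "", profile$role))
  structure(
    list(seed = as.integer(seed), profile = profile,
         n_chambers = as.integer(n_chambers),
         cells_per_chamber_init = as.integer(cells_per_chamber_init),
         t_end = t_end, t_onset = t_onset, dt_phase_min = dt_phase_min,
         dt_fluor_min = dt_fluor_min,
         chamber_capacity_area = chamber_capacity_area,
         condition_id = condition_id, experiment_id = experiment_id),
    class = "sim_config")
}

# cumulative specific-growth integral M(t) = int_0^t mu(s) ds for one
# condition; vectorized over t
growth_integral <- function(t, role, mu_excess, mu_limitation,
                            mu_ini, mu_adapted, t_onset, t_adapt) {
  if (role == "excess_control") return(mu_excess * t)
  if (role == "limitation_control") return(mu_limitation * t)
  tb <- t_onset + t_adapt
  ifelse(t <= t_onset, mu_excess * t,
         ifelse(t <= tb, mu_excess * t_onset + mu_ini * (t - t_onset),
                mu_excess * t_onset + mu_ini * t_adapt +
                  mu_adapted * (t - tb)))
}

# division-threshold multiplier: baseline before onset, relaxing
# linearly to the condition's size factor during the last 10% of the
# adaptation window (size adapts only as growth approaches mu_max)
size_factor_at <- function(t, role, s_target, t_onset, t_adapt) {
  if (role == "excess_control") return(rep(1, length(t)))
  if (role == "limitation_control") return(rep(s_target, length(t)))
  t0 <- t_onset + 0.9 * t_adapt
  t1 <- t_onset + t_adapt
  out <- rep(1, length(t))
  if (t1 > t0) {
    ramp <- t > t0 & t < t1
    out[ramp] <- 1 + (s_target - 1) * (t[ramp] - t0) / (t1 - t0)
  }
  out[t >= t1] <- s_target
  out
}

#' Simulate a dMSCC condition
#'
#' Agent-based simulation of budding microcolonies in monolayer
#' chambers.  Each cell grows exponentially in area at the
#' condition-level rate: `mu_excess` during the pre-phase, a reduced
#' initial rate `mu_ini_fraction(f) * mu_adapted` during the adaptation
#' window after onset, and the adapted rate `dose_response_mu(f) *
#' mu_excess` afterwards.  A cell divides when its area reaches the
#' (condition- and time-dependent) division threshold, splitting
#' `bud_fraction` of its area into a new cell; divisions conserve area,
#' so the total colony area is exactly piecewise-exponential.  Sensor
#' gray values are drawn so the uvGFP/GFP (QUEEN-2m, ATP) and CFP/RFP
#' (GlyRNA, FBP) ratios have condition medians given by the
#' dose-response maps, with multiplicative lognormal noise; subpopulation
#' levels are inherited at division.  A chamber whose total area exceeds
#' the capacity is truncated at that frame (a warning reports how many).
#'
#' @param config A [sim_config()].
#' @param params A [strain_params()].
#' @return A `cell_table` data frame with one row per detected cell per
#'   frame: `strain`, `condition_id`, `experiment_id`, `role`,
#'   `excess_s`, `limitation_s`, `array_index`, `chamber_index`,
#'   `frame`, `time_h`, `cell_id`, `area_um2`, `gray_rfp`, `gray_gfp`,
#'   `gray_cfp`, `gray_uvgfp` (fluorescence columns are `NA` except at
#'   fluorescence frames) and `subpop` (generator ground truth).  The
#'   generator's ground-truth parameters are attached as attribute
#'   `"ground_truth"`.
#' @export
simulate_experiment <- function(config, params) {
  stopifnot(inherits(config, "sim_config"), inherits(params, "strain_params"))
  prof <- config$profile
  role <- prof$role
  f <- effective_excess_fraction(prof)
  mu_adapted <- params$dose_response_mu(f) * params$mu_excess
  mu_ini <- params$mu_ini_fraction(f) * mu_adapted
  t_adapt <- if (role == "dynamic") params$t_adapt(f) else 0
  s_target <- if (role == "limitation_control") params$size_limitation_control
              else if (role == "excess_control") 1
              else params$dose_response_size(f)
  atp_of <- function(fe) params$dose_response_atp(fe)
  fbp_of <- function(fe) params$dose_response_fbp(fe)

  frames <- 0:floor(config$t_end * 60 / config$dt_phase_min)
  times <- frames * config$dt_phase_min / 60
  fluor_every <- config$dt_fluor_min %/% config$dt_phase_min
  is_fluor <- frames %% fluor_every == 0L
  # effective excess fraction driving the sensors at each frame
  f_sens <- if (role == "excess_control") rep(1, length(times))
            else if (role == "limitation_control") rep(0, length(times))
            else ifelse(times < config$t_onset, 1, f)
  M <- growth_integral(times, role, params$mu_excess, params$mu_limitation,
                       mu_ini, mu_adapted, config$t_onset, t_adapt)
  thr <- params$division_area *
    size_factor_at(times, role, s_target, config$t_onset, t_adapt)

  arrays <- switch(role, excess_control = 1L, limitation_control = 7L,
                   c(3L, 4L, 5L))
  gs <- params$gray_scales
  sub <- params$atp_subpops
  out <- params$fbp_outliers
  chambers <- vector("list", config$n_chambers)
  n_truncated <- 0L

  for (ch in seq_len(config$n_chambers)) {
    set.seed(chamber_seed(config$seed, ch))
    lo <- config$cells_per_chamber_init[1]
    hi <- config$cells_per_chamber_init[2]
    n0 <- if (hi > lo) sample(seq(lo, hi), 1) else lo
    areas <- stats::runif(n0, 0.40, 0.60) * params$division_area
    thr_jit <- lognorm_noise(n0, params$division_cv)
    atp_mult <- rep(1, n0)
    subpop <- rep("main", n0)
    if (!is.null(sub)) {
      hi_cell <- stats::runif(n0) < sub$fraction_high
      atp_mult <- ifelse(hi_cell, sub$level_high, sub$level_low)
      subpop <- ifelse(hi_cell, "atp_high", "atp_low")
    }
    fbp_mult <- rep(1, n0)
    if (!is.null(out)) {
      hi_fbp <- stats::runif(n0) < out$fraction
      fbp_mult <- ifelse(hi_fbp, out$level, 1)
      subpop <- ifelse(hi_fbp, "fbp_high", subpop)
    }

    cols <- vector("list", length(frames))
    for (j in seq_along(frames)) {
      if (j > 1) areas <- areas * exp(M[j] - M[j - 1])
      div <- which(areas >= thr[j] * thr_jit)
      if (length(div)) {
        buds <- params$bud_fraction * areas[div]
        areas[div] <- areas[div] - buds
        areas <- c(areas, buds)
        thr_jit[div] <- lognorm_noise(length(div), params$division_cv)
        thr_jit <- c(thr_jit, lognorm_noise(length(div), params$division_cv))
        atp_mult <- c(atp_mult, atp_mult[div])
        fbp_mult <- c(fbp_mult, fbp_mult[div])
        subpop <- c(subpop, subpop[div])
      }
      if (sum(areas) > config$chamber_capacity_area) {
        n_truncated <- n_truncated + 1L
        break
      }
      n <- length(areas)
      if (is_fluor[j]) {
        q_target <- atp_of(f_sens[j]) * atp_mult
        g_target <- fbp_of(f_sens[j]) * fbp_mult
        rfp <- gs[["rfp"]] * lognorm_noise(n, params$noise_cv_fluor)
        gfp <- gs[["gfp"]] * lognorm_noise(n, params$noise_cv_fluor)
        cfp <- gs[["cfp"]] * g_target * lognorm_noise(n, params$noise_cv_fluor)
        uvg <- gs[["uvgfp"]] * q_target *
          lognorm_noise(n, params$noise_cv_fluor)
      } else {
        rfp <- gfp <- cfp <- uvg <- rep(NA_real_, n)
      }
      cols[[j]] <- list(
        frame = rep(frames[j], n), time_h = rep(times[j], n),
        cell_id = sprintf("c%03d_f%03d_%04d", ch, frames[j], seq_len(n)),
        area_um2 = areas * lognorm_noise(n, params$noise_cv_area),
        gray_rfp = rfp, gray_gfp = gfp, gray_cfp = cfp, gray_uvgfp = uvg,
        subpop = subpop)
    }
    cols <- cols[!vapply(cols, is.null, logical(1))]
    bind <- function(nm) do.call(c, lapply(cols, `[[`, nm))
    nrows <- length(bind("frame"))
    chambers[[ch]] <- data.frame(
      array_index = rep(arrays[((ceiling(ch / 10) - 1) %% length(arrays)) + 1],
                        nrows),
      chamber_index = rep(((ch - 1L) %% 10L) + 1L, nrows),
      frame = bind("frame"), time_h = bind("time_h"),
      cell_id = bind("cell_id"), area_um2 = bind("area_um2"),
      gray_rfp = bind("gray_rfp"), gray_gfp = bind("gray_gfp"),
      gray_cfp = bind("gray_cfp"), gray_uvgfp = bind("gray_uvgfp"),
      subpop = bind("subpop"), stringsAsFactors = FALSE)
  }
  if (n_truncated > 0)
    warning(sprintf(
      "%d chamber(s) exceeded the chamber capacity area and were truncated",
      n_truncated), call. = FALSE)

  tab <- do.call(rbind, chambers)
  tab <- cbind(
    data.frame(strain = params$name, condition_id = config$condition_id,
               experiment_id = config$experiment_id, role = role,
               excess_s = prof$excess_s, limitation_s = prof$limitation_s,
               stringsAsFactors = FALSE)[rep(1, nrow(tab)), , drop = FALSE],
    tab)
  rownames(tab) <- NULL
  class(tab) <- c("cell_table", "data.frame")
  attr(tab, "ground_truth") <- list(
    strain = params$name, condition_id = config$condition_id, role = role,
    excess_s = prof$excess_s, limitation_s = prof$limitation_s, f = f,
    mu_excess = params$mu_excess, mu_limitation = params$mu_limitation,
    mu_adapted = mu_adapted, mu_ini = mu_ini, t_adapt = t_adapt,
    t_onset = config$t_onset, size_factor = s_target,
    atp_level = atp_of(if (role == "dynamic") f else
      if (role == "excess_control") 1 else 0),
    fbp_level = fbp_of(if (role == "dynamic") f else
      if (role == "excess_control") 1 else 0),
    seed = config$seed, n_chambers = config$n_chambers)
  tab
}

#' Export a cell table to CSV with a ground-truth JSON sidecar
#'
#' Writes the long-format per-cell per-frame table with the documented
#' column schema (missing fluorescence values as empty fields).  The
#' generator's ground-truth parameters (attribute `"ground_truth"`, or
#' the `ground_truth` argument) are written to `<path>.json` so that
#' parameter-recovery tests can compare pipeline estimates to the truth.
#'
#' @param records A `cell_table` (see [simulate_experiment()]).
#' @param path CSV output path.
#' @param ground_truth Ground-truth list; defaults to the attribute on
#'   `records`.
#' @param keep_subpop Keep the generator-only `subpop` column?  Dropped
#'   by default, matching segmentation output.
#' @return `path`, invisibly.
#' @export
export_cell_table <- function(records, path,
                              ground_truth = attr(records, "ground_truth"),
                              keep_subpop = FALSE) {
  if (is.null(records) || nrow(records) == 0)
    stop("'records' must be a non-empty cell table", call. = FALSE)
  df <- as.data.frame(records)
  if (!keep_subpop) df$subpop <- NULL
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("failed to write cell table to '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  if (!is.null(ground_truth))
    jsonlite::write_json(ground_truth, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
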