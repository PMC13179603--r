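# shared fixtures, all built in code

# strip every stochastic element from a strain calibration
noise_free <- function(params) {
  params$noise_cv_area <- 0
  params$noise_cv_fluor <- 0
  params$division_cv <- 0
  params
}

# growth series built directly from vectors
make_series <- function(time_h, total_area, cell_count = 1L) {
  structure(data.frame(time_h = time_h, total_area = total_area,
                       cell_count = cell_count),
            class = c("growth_series", "data.frame"))
}

# exact two-phase piecewise log-linear colony series (8-min cadence)
piecewise_series <- function(mu1, mu2, t_break, t_end = 18, a0 = 60,
                             mu0 = 0.2, t_onset = 4) {
  tt <- seq(0, t_end, by = 8 / 60)
  loga <- log(a0) + ifelse(
    tt <= t_onset, mu0 * tt,
    ifelse(tt <= t_break, mu0 * t_onset + mu1 * (tt - t_onset),
           mu0 * t_onset + mu1 * (t_break - t_onset) + mu2 * (tt - t_break)))
  make_series(tt, exp(loga))
}

simulate_cond <- function(strain, excess_s, seed, n_chambers = 10, ...) {
  params <- default_strain_params(strain)
  prof <- make_profile(excess_s, 30 - excess_s)
  suppressWarnings(simulate_experiment(
    sim_config(seed, prof, n_chambers = n_chambers, ...), params))
}

analyze_quiet <- function(records, ...) {
  suppressMessages(analyze_condition(records, ...))
}
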