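# Condition-sweep orchestration and reporting: run the full pipeline
# across 2 s-stepped excess durations, assemble per-condition metric
# tables, spline summaries and deterministic report files.

#' Sweep configuration
#'
#' Declares the strains, the 2 s-stepped dynamic conditions, replicate
#' seeds and analysis windows of a full synthetic condition sweep.
#' Constant-excess and constant-limitation controls are always included
#' per strain and seed.
#'
#' @param strains Character vector of strain labels understood by
#'   [default_strain_params()].
#' @param excess_s Excess durations of the dynamic conditions, seconds.
#' @param seeds Integer vector of replicate master seeds.
#' @param n_chambers Chambers per condition.
#' @param period_s Oscillation period, seconds.
#' @param t_end,t_onset Cultivation end and dynamics onset, h.
#' @param window_max_h,window_ini_h Sliding / initial fit window
#'   lengths, h.
#' @param stat_window Fixed window for biosensor and size statistics, h.
#' @param max_chamber_index Chamber filter cut-off.
#' @param experiment_id Label recorded in provenance.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(strains = c("CEN.PK113-7D", "Ethanol Red", "PE2"),
                         excess_s = seq(3, 27, by = 2), seeds = 1L,
                         n_chambers = 20, period_s = 30, t_end = 18,
                         t_onset = 4, window_max_h = 3, window_ini_h = 1,
                         stat_window = c(10, 18), max_chamber_index = 10,
                         experiment_id = "sweep") {
  stopifnot(length(strains) >= 1, length(seeds) >= 1,
            all(excess_s > 0), all(excess_s < period_s))
  structure(
    list(strains = strains, excess_s = excess_s, seeds = as.integer(seeds),
         n_chambers = n_chambers, period_s = period_s, t_end = t_end,
         t_onset = t_onset, window_max_h = window_max_h,
         window_ini_h = window_ini_h, stat_window = stat_window,
         max_chamber_index = max_chamber_index,
         experiment_id = experiment_id),
    class = "sweep_config")
}

#' Analyze one pooled condition table
#'
#' Runs the growth and population-statistics path on one condition:
#' chamber filter, total-area series, sliding-window maximal rate,
#' initial rate, adaptation time, and the three population summaries.
#'
#' @param records A `cell_table` for one condition.
#' @param t_onset Onset of the dynamics, h.
#' @param window_max_h,window_ini_h Fit window lengths, h.
#' @param stat_window Biosensor/size window, h.
#' @param max_chamber_index Chamber filter cut-off.
#' @return A list: `series`, `fit_max`, `fit_ini`, `adaptation`,
#'   `queen`, `glyrna`, `size` (the last three are `pop_summary`
#'   objects).
#' @export
analyze_condition <- function(records, t_onset = 4, window_max_h = 3,
                              window_ini_h = 1, stat_window = c(10, 18),
                              max_chamber_index = 10) {
  tab <- suppressMessages(filter_chambers(records, max_chamber_index))
  tab <- suppressWarnings(pool_condition(tab))
  series <- growth_series(tab)
  fit_max <- mu_max_sliding(series, t_onset, window_h = window_max_h)
  fit_ini <- mu_ini(series, t_onset, window_h = window_ini_h)
  adapt <- adaptation_time(fit_ini, fit_max, t_onset)
  list(series = series, fit_max = fit_max, fit_ini = fit_ini,
       adaptation = adapt,
       queen = pop_summary(tab, "queen_ratio", stat_window),
       glyrna = pop_summary(tab, "glyrna_ratio", stat_window),
       size = pop_summary(tab, "area_um2", stat_window))
}

#' Run a full synthetic condition sweep
#'
#' For every strain and replicate seed, simulates the excess control,
#' the limitation control and every dynamic condition, runs the full
#' pipeline (simulate, chamber filter, pool, growth analysis,
#' population statistics) and normalizes every metric to the excess
#' control of the same strain and seed.
#'
#' @param config A [sweep_config()].
#' @return An object of class `sweep_result`: `rows`, a data frame with
#'   one row per strain x condition x seed holding `mu_max`, `mu_ini`,
#'   `norm_mu_max`, `t_adapt`, `mu_ratio`, `gate_passed`,
#'   `queen_norm`, `glyrna_norm`, `size_norm`, the time-weighted
#'   baseline `mu_tw` and `s_eff` (g/L); plus `config`.
#' @export
run_sweep <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  rows <- list()
  for (strain in config$strains) {
    params <- default_strain_params(strain)
    for (seed in config$seeds) {
      sim_one <- function(profile) {
        cfg <- sim_config(seed, profile, n_chambers = config$n_chambers,
                          t_end = config$t_end, t_onset = config$t_onset,
                          experiment_id = config$experiment_id)
        suppressWarnings(simulate_experiment(cfg, params))
      }
      ana_one <- function(records) {
        suppressMessages(analyze_condition(
          records, t_onset = config$t_onset,
          window_max_h = config$window_max_h,
          window_ini_h = config$window_ini_h,
          stat_window = config$stat_window,
          max_chamber_index = config$max_chamber_index))
      }
      ctrl_exc <- ana_one(sim_one(make_profile(config$period_s, 0,
                                               config$period_s)))
      ctrl_lim <- ana_one(sim_one(make_profile(0, config$period_s,
                                               config$period_s)))
      row_of <- function(ana, profile) {
        f <- duty_cycle(profile)
        # adaptation is defined relative to the onset of the dynamics,
        # so constant-condition controls never report one
        is_ctrl <- profile$role != "dynamic"
        data.frame(
          strain = strain, seed = seed, excess_s = profile$excess_s,
          limitation_s = profile$limitation_s, role = profile$role, f = f,
          mu_max = ana$fit_max$slope, mu_ini = ana$fit_ini$slope,
          norm_mu_max = normalize_mu(ana$fit_max$slope,
                                     ctrl_exc$fit_max$slope),
          t_adapt = if (is_ctrl) 0 else ana$adaptation$t_adapt,
          mu_ratio = ana$adaptation$mu_ratio,
          gate_passed = if (is_ctrl) FALSE else ana$adaptation$gate_passed,
          queen_norm = normalize_summary(ana$queen,
                                         ctrl_exc$queen)$normalized,
          glyrna_norm = normalize_summary(ana$glyrna,
                                          ctrl_exc$glyrna)$normalized,
          size_norm = normalize_summary(ana$size, ctrl_exc$size)$normalized,
          mu_tw = time_weighted_mu(ctrl_exc$fit_max$slope,
                                   ctrl_lim$fit_max$slope, profile),
          s_eff = effective_substrate(profile),
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1]] <-
        row_of(ctrl_exc, make_profile(config$period_s, 0, config$period_s))
      rows[[length(rows) + 1]] <-
        row_of(ctrl_lim, make_profile(0, config$period_s, config$period_s))
      for (e in config$excess_s) {
        profile <- make_profile(e, config$period_s - e, config$period_s)
        rows[[length(rows) + 1]] <- row_of(ana_one(sim_one(profile)), profile)
      }
    }
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  structure(list(rows = rows, config = config), class = "sweep_result")
}

#' Replicate means and a shape-preserving spline through a sweep metric
#'
#' Averages replicate values per excess duration, then interpolates the
#' means with a monotone (Fritsch-Carlson) cubic sampled on a fine grid
#' -- the curve drawn through dose-response panels.  With fewer than 3
#' distinct support points only the means are returned, with a warning.
#'
#' @param excess_s Excess durations, seconds (replicates repeated).
#' @param value Metric values.
#' @param n_grid Number of grid samples (default 101).
#' @return A list: `support`, `means`, and (when interpolated) `grid_x`,
#'   `grid_y`, `interpolant`.
#' @export
spline_summary <- function(excess_s, value, n_grid = 101) {
  stopifnot(length(excess_s) == length(value), length(value) >= 1)
  means <- tapply(value, excess_s, mean)
  xs <- as.numeric(names(means))
  ord <- order(xs)
  xs <- xs[ord]
  ms <- as.numeric(means)[ord]
  if (length(xs) < 3) {
    warning("fewer than 3 distinct excess durations; returning point means",
            call. = FALSE)
    return(list(support = xs, means = ms, grid_x = NULL, grid_y = NULL,
                interpolant = NULL))
  }
  monotone <- all(diff(ms) >= 0) || all(diff(ms) <= 0)
  fn <- stats::splinefun(xs, ms,
                         method = if (monotone) "hyman" else "monoH.FC")
  grid <- seq(min(xs), max(xs), length.out = n_grid)
  list(support = xs, means = ms, grid_x = grid, grid_y = fn(grid),
       interpolant = fn)
}

#' Write a sweep report: tidy TSV plus JSON provenance
#'
#' Emits a tidy long table (one row per strain x condition x seed x
#' metric) and a JSON file with the configuration, its hash, the seeds
#' and the package version.  Output bytes are deterministic for a fixed
#' sweep.
#'
#' @param sweep A [run_sweep()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(sweep, dir, prefix = "sweep") {
  stopifnot(inherits(sweep, "sweep_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- sweep$rows
  metrics <- c("mu_max", "mu_ini", "norm_mu_max", "t_adapt", "mu_ratio",
               "queen_norm", "glyrna_norm", "size_norm", "mu_tw", "s_eff")
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(strain = rows$strain, excess_s = rows$excess_s,
               role = rows$role, seed = rows$seed,
               gate_passed = rows$gate_passed, metric = m,
               value = rows[[m]], stringsAsFactors = FALSE)
  }))
  long <- long[order(long$strain, long$excess_s, long$seed, long$metric), ]
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  utils::write.table(format(long, digits = 10, trim = TRUE, scientific = FALSE),
                     tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- unclass(sweep$config)
  prov <- list(package = "dmscc",
               version = as.character(utils::packageVersion("dmscc")),
               config = cfg, config_hash = config_hash(cfg),
               seeds = cfg$seeds)
  json <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(prov, json, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}
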