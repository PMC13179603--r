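test_that("excess fraction follows the duty cycle", {
  expect_equal(effective_excess_fraction(make_profile(3, 27)), 0.1)
  expect_equal(effective_excess_fraction(make_profile(30, 0)), 1)
  expect_equal(effective_excess_fraction(make_profile(9, 21)), 0.3)
})

test_that("default calibrations pass through the printed anchors", {
  cen <- default_strain_params("CEN.PK113-7D")
  er <- default_strain_params("Ethanol Red")
  pe2 <- default_strain_params("PE2")
  expect_equal(cen$dose_response_mu(0.1), 0.5)
  expect_equal(er$dose_response_mu(0.1), 0.5)
  expect_equal(pe2$dose_response_mu(0.1), 0.5)
  expect_equal(cen$dose_response_atp(0), 0.9)
  expect_equal(pe2$dose_response_atp(0), 0.9)
  expect_equal(er$dose_response_atp(0), 0.7)
  for (p in list(cen, er, pe2))
    expect_equal(p$dose_response_fbp(0) / p$dose_response_fbp(1), 1.4)
  expect_equal(er$dose_response_size(0.1), 0.7)
  expect_gt(er$mu_excess, cen$mu_excess)  # growth ranking
  expect_gt(cen$mu_excess, pe2$mu_excess)
  expect_false(is.null(er$atp_subpops))
  expect_false(is.null(pe2$fbp_outliers))
  expect_error(default_strain_params("S288C"), "arg")
})

test_that("calibration maps are monotone and normalized at f = 1", {
  grid <- seq(0, 1, by = 0.01)
  for (strain in c("CEN.PK113-7D", "Ethanol Red", "PE2")) {
    p <- default_strain_params(strain)
    for (nm in c("dose_response_mu", "dose_response_atp",
                 "dose_response_size", "mu_ini_fraction")) {
      v <- p[[nm]](grid)
      expect_true(all(diff(v) >= -1e-9), label = paste(strain, nm))
      expect_equal(p[[nm]](1), 1)
    }
    expect_true(all(diff(p$dose_response_fbp(grid)) <= 1e-9))
    expect_true(all(diff(p$t_adapt(grid)) <= 1e-9))
  }
})

test_that("strain_params rejects non-monotone maps and bad bud fractions", {
  p <- default_strain_params("PE2")
  bad <- function(f) 1 - 0.5 * f  # decreasing where increase is required
  expect_error(
    strain_params("x", 0.2, 0.05, dose_response_mu = bad,
                  dose_response_atp = p$dose_response_atp,
                  dose_response_fbp = p$dose_response_fbp,
                  dose_response_size = p$dose_response_size,
                  mu_ini_fraction = p$mu_ini_fraction, t_adapt = p$t_adapt),
    "monotone")
  expect_error(
    strain_params("x", 0.2, 0.05, dose_response_mu = p$dose_response_mu,
                  dose_response_atp = p$dose_response_atp,
                  dose_response_fbp = p$dose_response_fbp,
                  dose_response_size = p$dose_response_size,
                  mu_ini_fraction = p$mu_ini_fraction, t_adapt = p$t_adapt,
                  bud_fraction = 0.6),
    "bud_fraction")
})

test_that("noise-free constant-excess colonies grow exactly exponentially", {
  params <- noise_free(default_strain_params("CEN.PK113-7D"))
  cfg <- sim_config(7, make_profile(30, 0), n_chambers = 1,
                    cells_per_chamber_init = c(1, 1))
  tab <- simulate_experiment(cfg, params)
  s <- growth_series(tab)
  dt <- diff(s$time_h)
  ratios <- s$total_area[-1] / s$total_area[-nrow(s)]
  # exact exponential growth of the total area, divisions included
  expect_equal(ratios, exp(params$mu_excess * dt), tolerance = 1e-12)
})

test_that("noise-free dynamic colonies are piecewise log-linear with the configured breakpoints", {
  params <- noise_free(default_strain_params("Ethanol Red"))
  cfg <- sim_config(11, make_profile(9, 21), n_chambers = 1,
                    cells_per_chamber_init = c(2, 2))
  tab <- simulate_experiment(cfg, params)
  gt <- attr(tab, "ground_truth")
  expect_equal(gt$t_adapt, 3.1)
  s <- growth_series(tab)
  expected <- log(s$total_area[1]) + ifelse(
    s$time_h <= 4, params$mu_excess * s$time_h,
    ifelse(s$time_h <= 4 + gt$t_adapt,
           params$mu_excess * 4 + gt$mu_ini * (s$time_h - 4),
           params$mu_excess * 4 + gt$mu_ini * gt$t_adapt +
             gt$mu_adapted * (s$time_h - 4 - gt$t_adapt)))
  expect_equal(log(s$total_area), expected, tolerance = 1e-10)
})

test_that("the simulator is deterministic for a fixed seed", {
  params <- default_strain_params("PE2")
  cfg <- sim_config(42, make_profile(9, 21), n_chambers = 3)
  a <- simulate_experiment(cfg, params)
  b <- simulate_experiment(cfg, params)
  expect_identical(a, b)
})

test_that("per-chamber streams do not depend on the chamber count", {
  params <- default_strain_params("PE2")
  small <- simulate_experiment(
    sim_config(5, make_profile(15, 15), n_chambers = 2), params)
  large <- simulate_experiment(
    sim_config(5, make_profile(15, 15), n_chambers = 4), params)
  two <- function(tab) {
    d <- as.data.frame(tab)[tab$chamber_index <= 2, ]
    attr(d, "ground_truth") <- NULL
    rownames(d) <- NULL
    d
  }
  expect_equal(two(small), two(large))
})

test_that("more time in excess never decreases the end-of-run total area", {
  params <- noise_free(default_strain_params("CEN.PK113-7D"))
  ends <- vapply(c(3, 9, 15, 21, 27), function(e) {
    tab <- simulate_experiment(
      sim_config(3, make_profile(e, 30 - e), n_chambers = 2), params)
    sum(tab$area_um2[tab$time_h == max(tab$time_h)])
  }, numeric(1))
  expect_true(all(diff(ends) >= 0))
})

test_that("adapted growth beats the time-weighted constant-condition average", {
  grid <- seq(0.02, 0.98, by = 0.02)
  for (strain in c("CEN.PK113-7D", "Ethanol Red", "PE2")) {
    p <- default_strain_params(strain)
    chord <- grid + (1 - grid) * p$mu_limitation / p$mu_excess
    expect_true(all(p$dose_response_mu(grid) > chord), label = strain)
  }
})

test_that("ATP subpopulations are bimodal and heritable over generations", {
  params <- default_strain_params("Ethanol Red")
  tab <- simulate_experiment(
    sim_config(13, make_profile(30, 0), n_chambers = 10), params)
  sub <- params$atp_subpops
  q_scale <- params$gray_scales[["uvgfp"]] / params$gray_scales[["gfp"]]
  split_at <- q_scale * sqrt(sub$level_low * sub$level_high)
  fl <- tab[!is.na(tab$gray_uvgfp) & tab$time_h >= 10, ]
  for (tm in unique(fl$time_h)) {
    r <- queen_ratio(fl$gray_uvgfp[fl$time_h == tm],
                     fl$gray_gfp[fl$time_h == tm])
    lo <- r[r < split_at]
    hi <- r[r >= split_at]
    expect_gt(length(lo), 0)
    expect_gt(length(hi), 0)
    # modes sit at the configured levels (well separated vs. noise)
    expect_equal(median(lo), q_scale * sub$level_low, tolerance = 0.1)
    expect_equal(median(hi), q_scale * sub$level_high, tolerance = 0.1)
  }
  # labels are inherited: the high fraction stays near its seeded value
  frac <- tapply(fl$subpop == "atp_high", fl$time_h, mean)
  expect_true(all(abs(frac - sub$fraction_high) < 0.25))
  expect_lt(diff(range(frac)), 0.2)
})

test_that("cell-table export round-trips and encodes the imaging cadences", {
  params <- default_strain_params("CEN.PK113-7D")
  tab <- simulate_experiment(
    sim_config(2, make_profile(9, 21), n_chambers = 2), params)
  path <- file.path(tempdir(), "cells.csv")
  export_cell_table(tab, path)
  back <- read_cell_table(path)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$area_um2, tab$area_um2, tolerance = 1e-8)
  expect_false("subpop" %in% names(back))  # ground truth stripped on export
  # fluorescence only every 32 min = every 4th phase frame
  expect_true(all(is.na(back$gray_gfp[back$frame %% 4 != 0])))
  expect_true(all(!is.na(back$gray_gfp[back$frame %% 4 == 0])))
  # ground-truth sidecar carries the generator parameters for recovery
  gt <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(gt$t_adapt, attr(tab, "ground_truth")$t_adapt)
  expect_equal(gt$f, 0.3)
  unlink(c(path, paste0(path, ".json")))
})

test_that("chamber overflow truncates the record stream with a warning", {
  params <- noise_free(default_strain_params("Ethanol Red"))
  cfg <- sim_config(1, make_profile(30, 0), n_chambers = 1,
                    cells_per_chamber_init = c(3, 3),
                    chamber_capacity_area = 400)
  expect_warning(tab <- simulate_experiment(cfg, params), "truncated")
  expect_lt(max(tab$time_h), 18)
})
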