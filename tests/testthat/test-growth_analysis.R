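test_that("growth_series sums areas per frame and sorts by time", {
  tab <- data.frame(time_h = c(1, 0, 1, 0), area_um2 = c(30, 25, 30, 35))
  s <- growth_series(tab)
  expect_equal(s$time_h, c(0, 1))
  expect_equal(s$total_area, c(60, 60))
  expect_equal(s$cell_count, c(2L, 2L))
})

test_that("log-linear fits recover exact slopes with unit R-squared", {
  tt <- seq(0, 5, by = 8 / 60)
  s <- make_series(tt, 40 * exp(0.3 * tt))
  ft <- fit_log_linear(s, c(0, 5 + 1e-6))
  expect_equal(ft$slope, 0.3, tolerance = 1e-12)
  expect_equal(ft$r_squared, 1)
  flat <- fit_log_linear(make_series(tt, rep(50, length(tt))), c(0, 6))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 1)
  expect_error(fit_log_linear(s, c(0, 0.2)), "insufficient")
  # closed-open window: the end frame is excluded
  ft2 <- fit_log_linear(s, c(0, tt[4]))
  expect_equal(ft2$n_points, 3L)
})

test_that("fitted slopes sit within 3 standard errors of the truth under noise", {
  mu <- 0.3
  tt <- seq(0, 3, length.out = 23)
  cover <- vapply(1:200, function(i) {
    set.seed(i)
    a <- 50 * exp(mu * tt) * rlnorm(23, 0, 0.02)
    fit <- lm(log(a) ~ tt)
    abs(coef(fit)[2] - mu) <= 3 * summary(fit)$coefficients[2, 2]
  }, logical(1))
  expect_gte(mean(cover), 0.95)
})

test_that("sliding-window mu_max equals the brute-force window maximum", {
  # random piecewise-noisy series up to 150 frames, oracle by enumeration
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(60:150, 1)
    tt <- (seq_len(n) - 1) * 8 / 60
    loga <- cumsum(rnorm(n, mean = 0.02, sd = 0.01))
    s <- make_series(tt, exp(loga))
    got <- mu_max_sliding(s, t_onset = 1, window_h = 2)
    # independent oracle: every complete window, lm slope, earliest max
    starts <- tt[tt >= 1 & tt + 2 <= max(tt) + 1e-9]
    slopes <- vapply(starts, function(a) {
      sel <- tt >= a - 1e-9 & tt < a + 2 - 1e-9
      unname(coef(lm(loga[sel] ~ tt[sel]))[2])
    }, numeric(1))
    best <- which.max(slopes)
    expect_equal(got$slope, slopes[best], tolerance = 1e-9)
    expect_equal(got$window[1], starts[best])
  }
})

test_that("mu_max picks a window at or after the breakpoint of a two-phase series", {
  s <- piecewise_series(0.05, 0.1, t_break = 7.1)
  got <- mu_max_sliding(s, t_onset = 4, window_h = 3)
  expect_equal(got$slope, 0.1, tolerance = 1e-10)
  expect_gte(got$window[1], 7.1)
  # constant-slope series: the slope is that constant from any window
  sc <- make_series(seq(0, 18, by = 8 / 60),
                    30 * exp(0.2 * seq(0, 18, by = 8 / 60)))
  expect_equal(mu_max_sliding(sc, 4)$slope, 0.2, tolerance = 1e-10)
  short <- make_series(seq(0, 5, by = 8 / 60),
                       30 * exp(0.2 * seq(0, 5, by = 8 / 60)))
  expect_error(mu_max_sliding(short, 4, window_h = 3), "no complete window")
})

test_that("mu_ini fits the first post-onset hour and ignores divisions", {
  s <- piecewise_series(0.05, 0.1, t_break = 7.1)
  expect_equal(mu_ini(s, 4)$slope, 0.05, tolerance = 1e-10)
  expect_equal(mu_ini(s, 4)$n_points, 8L)  # 8-min cadence
  # a division conserves total area, so the series (and slope) is unchanged
})

test_that("adaptation time is the exact intersection of the two fits", {
  s <- piecewise_series(0.05, 0.1, t_break = 4 + 3.1)
  fit_i <- mu_ini(s, 4)
  fit_m <- mu_max_sliding(s, 4)
  ad <- adaptation_time(fit_i, fit_m, 4)
  expect_true(ad$gate_passed)
  expect_equal(ad$t_adapt, 3.1, tolerance = 1e-9)
  expect_equal(ad$mu_ratio, 0.5, tolerance = 1e-9)
})

test_that("the adaptation gate rejects near-equal growth phases", {
  f1 <- dmscc:::growth_fit(0.1, log(30), c(4, 5), 1, 8L)
  same <- adaptation_time(f1, f1, 4)
  expect_false(same$gate_passed)
  expect_equal(same$t_adapt, 0)
  f2 <- dmscc:::growth_fit(0.1 / 0.95, log(30), c(7, 10), 1, 22L)
  close_fits <- adaptation_time(f1, f2, 4)
  expect_false(close_fits$gate_passed)  # ratio 0.95 >= 0.9
  f3 <- dmscc:::growth_fit(0.2, log(30) - 0.2 * 10, c(7, 10), 1, 22L)
  ok <- adaptation_time(f1, f3, 4)
  expect_true(ok$gate_passed)
  expect_gte(ok$t_adapt, 0)
})

test_that("normalization and the time-weighted baseline follow their definitions", {
  expect_equal(normalize_mu(0.3, 0.3), 1)
  expect_equal(normalize_mu(0.15, 0.3), 0.5)
  expect_error(normalize_mu(0.1, 0), "positive")
  expect_equal(time_weighted_mu(0.3, 0.1, make_profile(15, 15)), 0.2)
  expect_equal(time_weighted_mu(0.3, 0.1, make_profile(30, 0)), 0.3)
  expect_equal(effective_substrate(make_profile(15, 15)), (50 + 0.01) / 2)
})

test_that("slopes, adaptation times and normalized values are scale invariant", {
  s <- piecewise_series(0.05, 0.1, t_break = 7.1)
  s2 <- make_series(s$time_h, s$total_area * 1e3)
  for (fn in list(function(x) mu_ini(x, 4)$slope,
                  function(x) mu_max_sliding(x, 4)$slope,
                  function(x) adaptation_time(mu_ini(x, 4),
                                              mu_max_sliding(x, 4),
                                              4)$t_adapt)) {
    expect_equal(fn(s2), fn(s), tolerance = 1e-9)
  }
})

test_that("Monod fitting recovers exact parameters and flags degenerate input", {
  S <- c(0.01, 0.1, 0.3, 1, 3, 10, 25, 50)
  mu <- 0.4 * S / (0.15 + S)
  got <- fit_monod(S, mu)
  expect_true(got$converged)
  expect_equal(got$mu_m, 0.4, tolerance = 1e-6)
  expect_equal(got$Ks, 0.15, tolerance = 1e-6)
  expect_equal(got$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_monod(c(1, 1, 2), c(0.1, 0.1, 0.2)), "3 distinct")
})
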