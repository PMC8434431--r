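# Linearization diagnostics, nonlinear fitting, model comparison.

test_that("loglog_powerlaw_fit recovers exact and limiting exponents", {
  # exact power law M = 2 t^0.5
  t <- c(1, 4, 9, 16)
  prof <- release_profile(t, 2 * sqrt(t))
  fit <- loglog_powerlaw_fit(prof, window = range(t))
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, log(2), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # noiseless Weibull data in the small-argument regime: the log-log
  # slope estimates beta to within 5 % (the OLS slope carries a small
  # downward curvature bias of order (t/tau)^beta / 2)
  tg1 <- seq(0.1, 1, length.out = 15)
  fit1 <- loglog_powerlaw_fit(noiseless_profile(p_nanofibers, tg1),
                              window = c(0.1, 1))
  expect_lt(abs(fit1$slope - 0.71) / 0.71, 0.05)
  tg2 <- seq(1, 8, length.out = 15)
  fit2 <- loglog_powerlaw_fit(noiseless_profile(p_colloids, tg2),
                              window = c(1, 8))
  expect_equal(fit2$slope, 2.67, tolerance = 0.05 / 2.67)
})

test_that("loglog_powerlaw_fit excludes unusable points and errors when few", {
  prof <- release_profile(c(0, 1, 2, 3, 4), c(0, 0, 1, 2, 3))
  expect_warning(fit <- loglog_powerlaw_fit(prof, window = c(0, 4)),
                 "excluded")
  expect_equal(fit$n_points, 3L)
  few <- release_profile(c(1, 2, 3), c(0, 0, 1))
  expect_error(suppressWarnings(loglog_powerlaw_fit(few, window = c(1, 3))),
               ">= 3 usable")
})

test_that("default_powerlaw_window applies the 60 % of M_inf bound", {
  prof <- release_profile(1:6, c(2, 5, 12, 20, 26, 27.5),
                          m_inf_hint = 27.8)
  w <- default_powerlaw_window(prof)
  expect_equal(w, c(1, 3))  # releases 2, 5, 12 are <= 0.6 * 27.8 = 16.68
  # all points below the bound -> full range
  low <- release_profile(1:5, c(1, 2, 3, 4, 5), m_inf_hint = 100)
  expect_equal(default_powerlaw_window(low), c(1, 5))
  # dense noiseless colloid curve: window end ~ inverse at 0.6 M_inf
  tg <- seq(0.5, 80, by = 0.25)
  wc <- default_powerlaw_window(noiseless_profile(p_colloids, tg))
  expect_equal(wc[2], weibull_inverse(0.6 * 15.1, p_colloids),
               tolerance = 0.25 / 30)
  sat <- release_profile(1:4, c(90, 95, 99, 100), m_inf_hint = 100)
  expect_error(default_powerlaw_window(sat), "no points")
})

test_that("weibull_plot_transform linearizes exactly", {
  # single-point identity: (tau_k, 63.2 % of M_inf) -> (ln tau_k, 0)
  p <- p_nanofibers
  tg <- c(1, p$tau_k, 30)
  prof <- noiseless_profile(p, tg)
  pts <- weibull_plot_transform(prof, m_inf = p$m_inf)
  expect_equal(pts$x[2], log(p$tau_k))
  expect_equal(pts$y[2], 0, tolerance = 1e-12)
  # collinearity: y = beta x - beta ln tau_k
  grid <- noiseless_profile(p, 1:80)
  tp <- weibull_plot_transform(grid, m_inf = p$m_inf)
  expect_equal(tp$y, p$beta * tp$x - p$beta * log(p$tau_k),
               tolerance = 1e-10)
  # exclusion bookkeeping: one zero-release and one at-saturation point
  mixed <- release_profile(c(0.5, 1, 2, 3, 4), c(0, 1, 2, 3, 30),
                           m_inf_hint = 10)
  tm <- weibull_plot_transform(mixed, m_inf = 10)
  expect_equal(attr(tm, "n_excluded"), 2L)
  expect_equal(nrow(tm), 3L)
  expect_error(weibull_plot_transform(
    release_profile(1:3, c(0, 0, 5)), m_inf = 10), ">= 3")
})

test_that("weibull_plot_fit slope equals beta on noiseless data", {
  fit <- weibull_plot_fit(noiseless_profile(p_nanofibers, 1:80),
                          m_inf = 27.8)
  expect_equal(fit$slope, 0.71, tolerance = 1e-10)
  expect_equal(fit$tau_k0, 10.51, tolerance = 1e-8)
  # keep (t/tau)^beta moderate: near saturation 1 - M/M_inf underflows
  # and the transform loses the information to recover beta exactly
  for (p in random_params(6, seed = 21L)) {
    tg <- seq(0.2 * p$tau_k, 2.5 * p$tau_k, length.out = 12)
    f <- weibull_plot_fit(noiseless_profile(p, tg), m_inf = p$m_inf)
    expect_equal(f$slope, p$beta, tolerance = 1e-6)
  }
})

test_that("weibull_plot_fit slope tolerates measurement noise", {
  prof <- generate_profile(p_colloids, sampling_schedule("uniform", 20),
                           noise_model(sd = 0.3, seed = 1))
  fit <- weibull_plot_fit(prof)
  expect_lt(abs(fit$slope - 2.67), 0.2)
})

test_that("fit_weibull_cdf recovers parameters from noiseless data", {
  tg <- exp(seq(log(0.25), log(80), length.out = 20))
  fit <- fit_weibull_cdf(noiseless_profile(p_nanofibers, tg),
                         m_inf = 27.8)
  expect_true(fit$converged)
  expect_true(fit$m_inf_fixed)
  expect_equal(fit$params$tau_k, 10.51, tolerance = 1e-6)
  expect_equal(fit$params$beta, 0.71, tolerance = 1e-6)
  expect_lt(fit$residual_rmse, 1e-6)
  expect_false("m_inf" %in% names(fit$param_ses))
  # free-saturation variant
  free <- fit_weibull_cdf(noiseless_profile(p_colloids, tg),
                          free_m_inf = TRUE)
  expect_equal(free$params$m_inf, 15.1, tolerance = 1e-5)
  expect_equal(free$params$beta, 2.67, tolerance = 1e-5)
  expect_true("m_inf" %in% names(free$param_ses))
})

test_that("noiseless round-trip recovery holds for random parameters", {
  for (p in random_params(6, seed = 31L)) {
    tg <- exp(seq(log(0.05 * p$tau_k), log(5 * p$tau_k),
                  length.out = 15))
    fit <- fit_weibull_cdf(noiseless_profile(p, tg), m_inf = p$m_inf)
    expect_true(fit$converged)
    expect_equal(fit$params$tau_k, p$tau_k, tolerance = 1e-6)
    expect_equal(fit$params$beta, p$beta, tolerance = 1e-6)
  }
})

test_that("fit_weibull_cdf recovers beta from noisy nanofiber data", {
  s <- sampling_schedule("log_spaced", 25, t_max = 80, t_min = 0.25)
  prof <- generate_profile(p_nanofibers, s, noise_model(0.5, 1234))
  fit <- fit_weibull_cdf(prof, m_inf = 27.8)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$beta - 0.71), 0.10)
})

test_that("recovery error shrinks as noise decreases", {
  s <- sampling_schedule("log_spaced", 20, t_max = 80, t_min = 0.25)
  rmse <- vapply(c(1.0, 0.5, 0.1), function(sd)
    recovery_experiment(p_nanofibers, 15, noise_model(sd, 11),
                        s)$rmse[["beta"]], numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("fitting is invariant to input-point order (via the CSV sorter)", {
  tg <- exp(seq(log(0.5), log(80), length.out = 15))
  prof <- noiseless_profile(p_colloids, tg)
  path <- withr::local_tempfile(fileext = ".csv")
  sh <- withr::with_seed(1, sample(length(tg)))
  writeLines(c("time_h,release_pct",
               sprintf("%.10f,%.10f", tg[sh],
                       weibull_cdf(tg, p_colloids)[sh])), path)
  reread <- read_profile_csv(path)
  f1 <- fit_weibull_cdf(prof, m_inf = 15.1)
  f2 <- fit_weibull_cdf(reread, m_inf = 15.1)
  expect_equal(f1$params$beta, f2$params$beta, tolerance = 1e-10)
})

test_that("goodness_of_fit follows the standard definitions", {
  prof <- release_profile(1:5, c(1, 3, 4, 6, 8))
  perfect <- goodness_of_fit(prof, prof$release)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$rmse, 0)
  at_mean <- goodness_of_fit(prof, rep(mean(prof$release), 5))
  expect_equal(at_mean$r_squared, 0)
  flat <- release_profile(1:4, rep(2, 4))
  expect_true(is.na(goodness_of_fit(flat, rep(2, 4))$r_squared))
  expect_error(goodness_of_fit(prof, 1:3), "length")
})

test_that("Weibull beats Higuchi (AICc) on sigmoidal synthetic data", {
  prof <- generate_profile(p_colloids, sampling_schedule("paperlike", 20),
                           noise_model(0.3, 7))
  cmp <- compare_models(prof, candidates = c("weibull", "higuchi"))
  expect_equal(cmp$best_model, "weibull")
  expect_lt(cmp$fits$weibull$gof$aicc, cmp$fits$higuchi$gof$aicc)
})

test_that("compare_models self-selects and survives candidate failure", {
  t <- 1:10
  zo <- release_profile(t, 2 * t)
  expect_equal(compare_models(zo)$best_model, "zero_order")
  sig <- generate_profile(p_colloids, sampling_schedule("paperlike", 20),
                          noise_model(0.3, 7))
  expect_equal(compare_models(sig)$best_model, "weibull")
  single <- compare_models(zo, candidates = "higuchi")
  expect_equal(single$best_model, "higuchi")
})

test_that("release_profile validates its invariants", {
  expect_error(release_profile(c(1, 2), c(1, 2)), "at least 3")
  expect_error(release_profile(c(1, 2, 2), 1:3), "strictly increasing")
  expect_error(release_profile(c(-1, 1, 2), 1:3), "negative sampling")
  expect_error(release_profile(1:3, c(-1, 1, 2)), "negative release")
  expect_error(release_profile(1:3, 1:2), "length")
})
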