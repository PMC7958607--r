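# Extended cosine model: curve evaluation, warm start, fitting, derived
# parameters, pseudo-F.

truth_params <- cosine_params(m = 0, amp = 5.9, alpha = -0.3, beta = 22,
                              phi = 14.8)
minute_grid <- function(days = 5) rep(((1:1440) - 0.5) / 60, days)

test_that("antilogistic_mean limits and identities hold", {
  p_flat <- cosine_params(1, 2, 0.3, 1e-9, 10)
  tt <- seq(0, 24, by = 0.5)
  expect_equal(antilogistic_mean(tt, p_flat), rep(2, length(tt)),
               tolerance = 1e-6)               # beta -> 0: flat at mesor
  p_sq <- cosine_params(0, 1, 0, 1000, 14)
  expect_equal(antilogistic_mean(14, p_sq), 1, tolerance = 1e-9)  # saturation
  # analytic mesor crossing: t = phi +/- (24/2pi) arccos(alpha)
  for (alpha in c(-0.7, -0.3, 0, 0.55)) {
    p <- cosine_params(0.4, 3, alpha, 8, 15)
    dt <- 24 / (2 * pi) * acos(alpha)
    expect_equal(antilogistic_mean(15 + dt, p), 0.4 + 1.5, tolerance = 1e-10)
    expect_equal(antilogistic_mean(15 - dt, p), 0.4 + 1.5, tolerance = 1e-10)
  }
  # 24-h periodicity
  p <- cosine_params(0.4, 3, -0.2, 8, 15)
  expect_equal(antilogistic_mean(tt, p), antilogistic_mean(tt + 48, p))
})

test_that("cosinor warm start recovers a pure cosine and stays in range", {
  tt <- minute_grid(2)
  y <- 3 + 1 * cos((tt - 14) * pi / 12)
  s <- epoch_series("C", "2020-01-01T00:00:00", rep(0L, length(tt)))
  s$log_counts <- y                      # counts irrelevant for the init
  init <- cosinor_init(s)
  expect_equal(init$m, 2, tolerance = 1e-6)      # M - A
  expect_equal(init$amp, 2, tolerance = 1e-6)    # 2A
  expect_equal(init$phi, 14, tolerance = 1e-6)
  # noise around a constant: small amplitude, phi finite in [0, 24)
  set.seed(31)
  for (i in 1:5) {
    s$log_counts <- rnorm(length(tt), 2, 0.3)
    init <- cosinor_init(s)
    expect_lt(init$amp, 0.1)
    expect_true(init$phi >= 0 && init$phi < 24)
  }
})

test_that("noiseless curves are recovered to high relative accuracy", {
  tt <- minute_grid(5)
  y <- antilogistic_mean(tt, truth_params)
  f <- fit_extended_cosine_xy(tt, y)
  expect_true(f$converged)
  expect_equal(f$params$m, 0, tolerance = 1e-4)
  expect_equal(f$params$amp, 5.9, tolerance = 1e-3 * 5.9)
  expect_equal(f$params$alpha, -0.3, tolerance = 1e-3 * 0.3)
  expect_equal(f$params$beta, 22, tolerance = 1e-3 * 22)
  expect_hours_equal(f$params$phi, 14.8, tol = 1e-3)
  expect_lt(f$rss_model, 1e-8)
})

test_that("fitting is invariant to epoch order and refuses scant data", {
  set.seed(55)
  tt <- minute_grid(2)
  y <- antilogistic_mean(tt, truth_params) + rnorm(length(tt), 0, 0.5)
  f1 <- fit_extended_cosine_xy(tt, y)
  perm <- sample(length(tt))
  f2 <- fit_extended_cosine_xy(tt[perm], y[perm])
  expect_equal(f1$params$phi, f2$params$phi, tolerance = 1e-6)
  expect_equal(f1$rss_model, f2$rss_model, tolerance = 1e-8)
  # under a day of wear time is an error
  s <- log_transform(quick_series(3, n_days = 1))
  s$wear <- rep(FALSE, length(s))
  s$wear[1:600] <- TRUE
  expect_error(fit_extended_cosine(s), "wear minutes",
               class = "rar_data_error")
})

test_that("derived crossing times follow the arccos geometry", {
  # alpha = 0: crossings exactly 6 h either side of the acrophase
  d <- derive_parameters(cosine_params(0, 2, 0, 10, 14), 1, 2, 100)
  expect_equal(d$up_mesor, 8)
  expect_equal(d$down_mesor, 20)
  expect_equal(d$mesor_log, 1)
  expect_equal(d$mesor_exp, exp(1))
  # alpha -> 1: the active period collapses onto the acrophase
  d2 <- derive_parameters(cosine_params(0, 2, 0.999, 10, 14), 1, 2, 100)
  expect_hours_equal(d2$up_mesor, 14, tol = 0.2)   # arccos(0.999) ~ 0.17 h
  expect_hours_equal(d2$down_mesor, 14, tol = 0.2)
  # cohort-mean geometry: alpha -0.3, phi 14.8 put the crossings near the
  # reported 7.5 / 22.0 pattern
  d3 <- derive_parameters(cosine_params(0, 2, -0.3, 10, 14.8), 1, 2, 100)
  expect_equal(d3$down_mesor, 21.96, tolerance = 1e-2)
  expect_equal(d3$up_mesor, 7.64, tolerance = 1e-2)
})

test_that("pseudo-F follows its formula and degenerate contracts", {
  expect_equal(pseudo_f_statistic(100, 100, 50), 0)
  expect_equal(pseudo_f_statistic(200, 100, 1005), 250)  # (100/4)/(100/1000)
  expect_warning(out <- pseudo_f_statistic(10, 0, 50), "infinite")
  expect_identical(out, Inf)
  expect_error(pseudo_f_statistic(1, 2, 50), class = "rar_domain_error")
  expect_error(pseudo_f_statistic(2, 1, 4), class = "rar_domain_error")
})

test_that("pseudo-F grows with the signal-to-noise ratio", {
  set.seed(77)
  tt <- minute_grid(2)
  fstats <- vapply(c(0.5, 1.5, 3, 6), function(amp) {
    p <- cosine_params(0.5, amp, -0.3, 22, 14.8)
    y <- antilogistic_mean(tt, p) + rnorm(length(tt), 0, 0.5)
    fit_extended_cosine_xy(tt, y)$pseudo_f
  }, numeric(1))
  expect_true(all(diff(fstats) > 0))
})

test_that("converged fits satisfy the mesor-crossing identity", {
  set.seed(88)
  tt <- minute_grid(3)
  for (i in 1:5) {
    p <- cosine_params(runif(1, 0, 1), runif(1, 3, 8), runif(1, -0.7, 0.5),
                       exp(runif(1, 1.5, 4)), runif(1, 12, 18))
    y <- antilogistic_mean(tt, p) + rnorm(length(tt), 0, 0.5)
    f <- fit_extended_cosine_xy(tt, y)
    if (!f$converged) next
    expect_lt(abs(antilogistic_mean(f$up_mesor, f$params) - f$mesor_log),
              1e-8)
    expect_lt(abs(antilogistic_mean(f$down_mesor, f$params) - f$mesor_log),
              1e-8)
    # fitted RSS never exceeds the cosinor warm start's RSS under f
    s <- epoch_series("X", "2020-01-01T00:00:00", rep(0L, length(tt)))
    s$log_counts <- y
    init <- cosinor_init(s)
    expect_lte(f$rss_model,
               sum((y - antilogistic_mean(tt, init))^2) + 1e-8)
  }
})
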