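# Synthetic cohort generator.

test_that("population draws honour truncation, degeneracy and the LLN", {
  cfg0 <- sim_config(n_participants = 8, param_sds = c(m = 0, amp = 0,
                                                       alpha = 0, ln_beta = 0,
                                                       phi = 0), seed = 2)
  ps <- sample_population_params(cfg0)
  expect_true(all(vapply(ps, `[[`, numeric(1), "phi") == ps[[1]]$phi))
  expect_true(all(vapply(ps, `[[`, numeric(1), "amp") == 5.9))
  # alpha always strictly inside (-1, 1) even with a wide SD
  cfg1 <- sim_config(n_participants = 400,
                     param_sds = c(m = 0.3, amp = 1.5, alpha = 0.8,
                                   ln_beta = 0.6, phi = 1.3), seed = 3)
  al <- vapply(sample_population_params(cfg1), `[[`, numeric(1), "alpha")
  expect_true(all(abs(al) < 1))
  # sample means near configured means at n = 1000 (within 3 SE)
  cfg2 <- sim_config(n_participants = 1000, seed = 44)
  ps2 <- sample_population_params(cfg2)
  phi <- vapply(ps2, `[[`, numeric(1), "phi")
  expect_lt(abs(mean(phi) - 14.8), 3 * 1.3 / sqrt(1000))
  m <- vapply(ps2, `[[`, numeric(1), "m")
  expect_lt(abs(mean(m) - 0.5), 3 * 0.3 / sqrt(1000))
  # infeasible truncation is rejected
  expect_error(sim_config(param_means = c(m = 0.5, amp = 5.9, alpha = 2,
                                          ln_beta = 3.1, phi = 14.8)),
               class = "rar_config_error")
})

test_that("simulated series follow the curve and are seed-reproducible", {
  p <- cosine_params(0.5, 5.9, -0.3, 1000, 14.8)
  cfg <- sim_config(n_participants = 1, n_days = 2, noise_sd = 0, seed = 5)
  set.seed(1); s <- simulate_epoch_series(p, cfg)
  # square-wave limit: peak counts reach exp(m + amp) - 1
  expect_equal(max(s$counts), round(exp(0.5 + 5.9) - 1))
  # same seed -> identical; different seed -> different
  cfg2 <- sim_config(n_participants = 1, n_days = 2, noise_sd = 0.5, seed = 5)
  set.seed(9); a <- simulate_epoch_series(p, cfg2)
  set.seed(9); b <- simulate_epoch_series(p, cfg2)
  set.seed(10); c_ <- simulate_epoch_series(p, cfg2)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts, c_$counts))
  # Monte-Carlo: mean log(count+1) within 1 h of the acrophase approaches
  # f(phi) (count quantisation keeps this approximate)
  p2 <- cosine_params(1, 5, -0.3, 22, 14.8)
  cfg3 <- sim_config(n_participants = 1, n_days = 30, epoch_seconds = 300,
                     noise_sd = 0.5, seed = 6)
  set.seed(11); s3 <- log_transform(simulate_epoch_series(p2, cfg3))
  hrs <- rarfatigue:::epoch_mid_hours(s3)
  sel <- abs(hrs - 14.8) < 0.5
  expect_equal(mean(s3$log_counts[sel]), antilogistic_mean(14.8, p2),
               tolerance = 0.08)
})

test_that("non-wear injection is detectable exactly when long enough", {
  p <- cosine_params(2.5, 4, -0.3, 22, 14.8)
  cfg <- sim_config(n_participants = 1, n_days = 2, noise_sd = 0.3,
                    nonwear_rate = 0, seed = 7)
  set.seed(12); s <- simulate_epoch_series(p, cfg)
  # rate 0: unchanged, empty mask
  out0 <- inject_nonwear(s, cfg)
  expect_identical(out0$series$counts, s$counts)
  expect_false(any(out0$truth_nonwear))
  # a 120-min block in an active stretch is recovered exactly by the
  # detector when the surrounding counts are nonzero
  s2 <- s
  idx <- 600:719                      # 10:00-12:00 on day 1, peak activity
  s2$counts[idx] <- 0L
  s2$counts[setdiff(500:820, idx)] <-
    pmax(1L, s2$counts[setdiff(500:820, idx)])
  det <- detect_nonwear_choi(s2)
  expect_true(all(!det$wear[idx]))
  expect_true(all(det$wear[setdiff(500:820, idx)]))
  # 60-min blocks stay below the window: recall 0 by design
  s3 <- s
  idx3 <- 660:719
  s3$counts[idx3] <- 0L
  s3$counts[setdiff(560:820, idx3)] <-
    pmax(1L, s3$counts[setdiff(560:820, idx3)])
  det3 <- detect_nonwear_choi(s3)
  expect_true(all(det3$wear[idx3]))
})

test_that("simulate_cohort ties outcomes, items and ground truth together", {
  cfg <- sim_config(n_participants = 30, n_days = 2, epoch_seconds = 300,
                    seed = 13)
  coh <- simulate_cohort(cfg)
  expect_identical(nrow(coh$truth), 30L)
  expect_identical(nrow(coh$participants), 30L)
  expect_length(coh$series, 30L)
  # items decompose the score exactly when nothing is missing
  items <- as.matrix(coh$participants[, sprintf("pfs_%02d", 1:10)])
  expect_identical(as.integer(rowSums(items)), coh$participants$pfs_score)
  expect_true(all(items >= 0 & items <= 5))
  # ground-truth derived quantities match the parameter geometry
  expect_equal(coh$truth$mesor_log, coh$truth$m + coh$truth$amp / 2)
  expect_hours_equal(coh$truth$down_mesor,
                     coh$truth$phi + 24 / (2 * pi) * acos(coh$truth$alpha))
  # outcome medians follow the configured linear model
  b <- attr(coh$truth, "outcome_coefs")
  expect_equal(coh$truth$pfs_median,
               b[["intercept"]] + b[["up_mesor"]] * coh$truth$up_mesor)
  # bit-reproducibility of the whole cohort given the seed
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh2$participants, coh$participants)
  expect_identical(coh2$series[[5]]$counts, coh$series[[5]]$counts)
})

test_that("fits on near-noiseless cohorts track the true parameters 1:1", {
  cfg <- sim_config(n_participants = 12, n_days = 6, epoch_seconds = 300,
                    noise_sd = 0.01,
                    param_means = c(m = 2, amp = 5.9, alpha = -0.3,
                                    ln_beta = 3.1, phi = 14.8), seed = 14)
  coh <- simulate_cohort(cfg)
  tab <- rar_parameter_table(lapply(coh$series, function(s)
    fit_extended_cosine(log_transform(truncate_to_midnights(s, 5)))))
  tr <- coh$truth[match(tab$participant_id, coh$truth$participant_id), ]
  # slope 1, intercept 0 regressions of fitted on true (quantisation keeps
  # this near, not exactly at, machine precision)
  for (v in c("amp", "alpha", "phi")) {
    cf <- coef(lm(tab[[v]] ~ tr[[v]]))
    expect_equal(unname(cf[2]), 1, tolerance = 0.01)
  }
  expect_lt(median(abs(tab$m - tr$m)), 0.02)
})
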