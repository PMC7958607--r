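# Antilogistic extended cosine model of the 24-h rest-activity rhythm.
#
# The mean curve on the log(counts + 1) scale is
#   f(t; theta) = m + amp * expit(beta * (cos((t - phi) * 2*pi/24) - alpha))
# with theta = (m, amp, alpha, beta, phi): minimum level, amplitude, width
# (alpha in (-1, 1); larger = narrower active period), steepness (beta > 0;
# large = square-wave transitions) and acrophase (phi, hours). The curve
# crosses its mesor level m + amp/2 exactly where cos((t - phi) 2pi/24)
# equals alpha, giving the up-mesor (rise) and down-mesor (settle) times.

#' Extended-cosine parameter set
#'
#' @param m minimum level on the log-count scale.
#' @param amp non-negative amplitude (log-count scale).
#' @param alpha width parameter, strictly inside (-1, 1).
#' @param beta positive steepness parameter (unitless).
#' @param phi acrophase in hours; reduced modulo 24.
#' @return an object of class `cosine_params`.
#' @export
cosine_params <- function(m, amp, alpha, beta, phi) {
  stopifnot(is.finite(m), is.finite(amp), is.finite(alpha), is.finite(beta),
            is.finite(phi))
  if (amp < 0) stop_rar("amp must be non-negative", "rar_domain_error")
  if (abs(alpha) >= 1)
    stop_rar("alpha must lie strictly inside (-1, 1)", "rar_domain_error")
  if (beta <= 0) stop_rar("beta must be positive", "rar_domain_error")
  structure(list(m = unname(m), amp = unname(amp), alpha = unname(alpha),
                 beta = unname(beta), phi = unname(mod24(phi))),
            class = "cosine_params")
}

#' @export
print.cosine_params <- function(x, ...) {
  cat(sprintf(
    "<cosine_params> m=%.3f amp=%.3f alpha=%.3f beta=%.3g phi=%.2fh\n",
    x$m, x$amp, x$alpha, x$beta, x$phi))
  invisible(x)
}

#' Evaluate the antilogistic extended cosine mean curve
#'
#' @param t time in hours (any real; the curve has period 24).
#' @param params a [cosine_params()].
#' @return mean log(counts + 1) at `t`.
#' @export
antilogistic_mean <- function(t, params) {
  params$m + params$amp *
    expit(params$beta * (cos((t - params$phi) * pi / 12) - params$alpha))
}

#' Standard-cosinor warm start
#'
#' Ordinary least squares of log counts on `cos` and `sin` of the 24-h
#' angular frequency (the linear reparameterisation of
#' `M + A cos((t - phi) 2pi/24)`), converted to extended-cosine starting
#' values `m0 = M - A`, `amp0 = 2A`, `alpha0 = 0`, `beta0 = 2`,
#' `phi0 = cosinor acrophase`.
#'
#' @param series an [epoch_series()] with wear mask and `log_counts`.
#' @return a [cosine_params()] starting point.
#' @export
cosinor_init <- function(series) {
  d <- fit_frame(series)
  w <- pi / 12
  X <- cbind(1, cos(w * d$t), sin(w * d$t))
  cf <- stats::lm.fit(X, d$y)$coefficients
  a <- cf[2L]; b <- cf[3L]
  A <- sqrt(a^2 + b^2)
  phi0 <- if (A > 0) mod24(atan2(b, a) / w) else 0
  cosine_params(m = cf[1L] - A, amp = max(2 * A, 1e-6), alpha = 0,
                beta = 2, phi = phi0)
}

# Wear epochs with log counts and hour-of-day midpoints.
fit_frame <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  if (is.null(series$log_counts))
    stop_rar("log_counts not populated; run log_transform() first",
             "rar_usage_error")
  keep <- if (is.null(series$wear)) rep(TRUE, length(series$counts))
          else series$wear
  list(t = epoch_mid_hours(series)[keep], y = series$log_counts[keep])
}

# Residual sum of squares and its analytic gradient in the optimisation
# parameterisation (m, amp, alpha, log beta, phi).
rar_objective <- function(par, t, y) {
  m <- par[1L]; amp <- par[2L]; alpha <- par[3L]
  beta <- exp(par[4L]); phi <- par[5L]
  ang <- (t - phi) * (pi / 12)
  cc <- cos(ang)
  e <- expit(beta * (cc - alpha))
  r <- y - (m + amp * e)
  sum(r * r)
}

rar_gradient <- function(par, t, y) {
  m <- par[1L]; amp <- par[2L]; alpha <- par[3L]
  beta <- exp(par[4L]); phi <- par[5L]
  ang <- (t - phi) * (pi / 12)
  cc <- cos(ang)
  u <- beta * (cc - alpha)
  e <- expit(u)
  r <- y - (m + amp * e)
  de <- e * (1 - e)
  g_m <- sum(r)
  g_amp <- sum(r * e)
  g_alpha <- sum(r * de) * (-beta) * amp
  g_lnb <- amp * sum(r * de * u)
  g_phi <- amp * beta * (pi / 12) * sum(r * de * sin(ang))
  -2 * c(g_m, g_amp, g_alpha, g_lnb, g_phi)
}

#' Fit the extended cosine model to one participant
#'
#' Bounded nonlinear least squares of `log(counts + 1)` at wear-epoch
#' midpoints on the antilogistic extended cosine curve: `alpha` in
#' `[-0.999, 0.999]`, `amp >= 0`, `beta` optimised on the log scale with
#' upper bound 1000 (its sampling distribution is heavily right-tailed),
#' `phi` unbounded then reduced modulo 24. Starts from the standard-cosinor
#' warm start; if the first start does not converge, `phi0 - 3` and
#' `phi0 + 3` hours are tried and the best residual sum of squares kept.
#' Every fit ends with one restart from its own optimum (L-BFGS-B with a
#' fresh Hessian approximation), which sharpens noiseless recovery.
#'
#' @param series an [epoch_series()] with wear mask and `log_counts`; must
#'   carry at least one full day (1440 minutes) of wear time.
#' @param init optional [cosine_params()] starting point.
#' @param control list passed to [stats::optim()]'s control (defaults:
#'   `factr = 1e4`, `maxit = 500`).
#' @return a `cosine_fit`: list with `params` ([cosine_params()]),
#'   `mesor_log`, `mesor_exp`, `up_mesor`, `down_mesor`, `pseudo_f`,
#'   `rss_model`, `rss_null`, `n_epochs`, `n_days_observed`, `converged`.
#' @export
fit_extended_cosine <- function(series, init = NULL, control = list()) {
  d <- fit_frame(series)
  wear_minutes <- length(d$t) * series$epoch_seconds / 60
  if (wear_minutes < 1440)
    stop_rar(sprintf(
      "participant '%s': %.0f wear minutes < one full day; cannot fit",
      series$participant_id, wear_minutes), "rar_data_error")
  out <- fit_extended_cosine_xy(d$t, d$y, init = init, control = control,
                                id = series$participant_id)
  out$n_days_observed <- length(d$t) * series$epoch_seconds / 86400
  out$participant_id <- series$participant_id
  out
}

#' Low-level extended-cosine fit on (time, log activity) pairs
#'
#' The workhorse behind [fit_extended_cosine()], exposed in the spirit of
#' `lm.fit`: fits the curve to arbitrary `(t, y)` observations (hours,
#' log-count scale) with no wear/validity handling. Useful for simulation
#' studies on exact, unquantised curve values.
#'
#' @param t hours of day (any reals; used modulo 24 via the cosine).
#' @param y log-scale observations.
#' @inheritParams fit_extended_cosine
#' @param id participant id used in warnings.
#' @return a `cosine_fit` (without `n_days_observed`).
#' @export
fit_extended_cosine_xy <- function(t, y, init = NULL, control = list(),
                                   id = "xy") {
  stopifnot(length(t) == length(y), length(y) > 5L)
  d <- list(t = t, y = y)
  if (is.null(init)) {
    w <- pi / 12
    X <- cbind(1, cos(w * t), sin(w * t))
    cf <- stats::lm.fit(X, y)$coefficients
    A <- sqrt(cf[2L]^2 + cf[3L]^2)
    init <- cosine_params(cf[1L] - A, max(2 * A, 1e-6), 0, 2,
                          if (A > 0) mod24(atan2(cf[3L], cf[2L]) / w) else 0)
  }
  ctl <- utils::modifyList(list(factr = 1e4, maxit = 500L), control)
  lower <- c(-Inf, 0, -0.999, log(1e-3), -Inf)
  upper <- c(Inf, Inf, 0.999, log(1000), Inf)
  run <- function(p0) {
    stats::optim(p0, rar_objective, rar_gradient, t = d$t, y = d$y,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = ctl)
  }
  p0 <- c(init$m, init$amp, min(max(init$alpha, -0.999), 0.999),
          log(min(max(init$beta, 1e-3), 1000)), init$phi)
  fit <- run(p0)
  if (fit$convergence != 0L) {
    for (dphi in c(-3, 3)) {
      alt <- run(p0 + c(0, 0, 0, 0, dphi))
      if (alt$value < fit$value) fit <- alt
    }
  }
  polish <- run(fit$par)                 # restart from the optimum
  if (polish$value <= fit$value) fit <- polish
  converged <- fit$convergence == 0L
  if (!converged)
    warning(sprintf("participant '%s': optimizer did not converge (%s)",
                    id, fit$message))
  pars <- cosine_params(fit$par[1L], fit$par[2L], fit$par[3L],
                        exp(fit$par[4L]), mod24(fit$par[5L]))
  rss_null <- sum((d$y - mean(d$y))^2)
  rss_model <- min(fit$value, rss_null)   # guard against a degenerate start
  out <- derive_parameters(pars, rss_model, rss_null, length(d$y))
  out$converged <- converged
  out
}

#' Derived timing and rhythmicity statistics
#'
#' From a fitted parameter set: mesor on the log scale (`m + amp/2`) and
#' exponentiated (`exp(m + amp/2)`), the mesor-crossing times
#' `up_mesor = phi - (24/2pi) arccos(alpha)` (estimated rise time) and
#' `down_mesor = phi + (24/2pi) arccos(alpha)` (both modulo 24), and the
#' pseudo-F rhythmicity statistic.
#'
#' @param params a [cosine_params()].
#' @param rss_model,rss_null residual sums of squares of the cosine and the
#'   constant-mean fits.
#' @param n_epochs number of epochs entering the fit.
#' @return a `cosine_fit` list (without `n_days_observed`/`converged`).
#' @export
derive_parameters <- function(params, rss_model, rss_null, n_epochs) {
  stopifnot(inherits(params, "cosine_params"))
  half_width <- HOURS_PER_RADIAN * acos(params$alpha)
  mesor_log <- params$m + params$amp / 2
  structure(
    list(params = params,
         mesor_log = mesor_log,
         mesor_exp = exp(mesor_log),
         up_mesor = mod24(params$phi - half_width),
         down_mesor = mod24(params$phi + half_width),
         pseudo_f = pseudo_f_statistic(rss_null, rss_model, n_epochs),
         rss_model = rss_model,
         rss_null = rss_null,
         n_epochs = n_epochs),
    class = "cosine_fit"
  )
}

#' @export
print.cosine_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    paste0("<cosine_fit>%s m=%.3f amp=%.3f alpha=%.3f beta=%.3g phi=%.2fh\n",
           "  mesor(log)=%.3f up=%.2fh down=%.2fh pseudo-F=%.1f%s\n"),
    if (!is.null(x$participant_id)) paste0(" ", x$participant_id) else "",
    p$m, p$amp, p$alpha, p$beta, p$phi,
    x$mesor_log, x$up_mesor, x$down_mesor, x$pseudo_f,
    if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}

#' Pseudo-F rhythmicity statistic
#'
#' `F = ((rss_null - rss_model)/(p - 1)) / (rss_model/(n - p))` with `p = 5`
#' model parameters; an F-ratio of the extended cosine fit against a
#' constant mean, used as a global index of rhythm robustness.
#'
#' @param rss_null,rss_model residual sums of squares (null >= model).
#' @param n_epochs number of observations; must exceed `p`.
#' @param p number of model parameters (default 5).
#' @return non-negative real; `Inf` with a warning when `rss_model` is zero.
#' @export
pseudo_f_statistic <- function(rss_null, rss_model, n_epochs, p = 5L) {
  if (rss_model > rss_null + 1e-8 * (1 + rss_null))
    stop_rar("rss_model exceeds rss_null", "rar_domain_error")
  if (n_epochs <= p)
    stop_rar("n_epochs must exceed the number of parameters",
             "rar_domain_error")
  if (rss_model == 0) {
    warning("rss_model is zero; pseudo-F is infinite")
    return(Inf)
  }
  max(0, (rss_null - rss_model) / (p - 1)) / (rss_model / (n_epochs - p))
}

#' Tabulate fits across participants
#'
#' One row per participant in the column layout written by the pipeline:
#' `participant_id, m, amp, alpha, beta, phi, mesor_log, mesor_exp,
#' up_mesor, down_mesor, pseudo_f, n_epochs, n_days_observed, converged`.
#'
#' @param fits list of `cosine_fit` objects.
#' @return data frame.
#' @export
rar_parameter_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(
      participant_id = f$participant_id, m = f$params$m, amp = f$params$amp,
      alpha = f$params$alpha, beta = f$params$beta, phi = f$params$phi,
      mesor_log = f$mesor_log, mesor_exp = f$mesor_exp,
      up_mesor = f$up_mesor, down_mesor = f$down_mesor,
      pseudo_f = f$pseudo_f, n_epochs = f$n_epochs,
      n_days_observed = f$n_days_observed, converged = f$converged,
      row.names = NULL
    )
  }))
}
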