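# Quantile (median) regression by minimising the check loss
#   sum_i rho_tau(y_i - x_i'b),  rho_tau(u) = u * (tau - 1[u < 0]),
# with a majorize-minimize scheme (iteratively reweighted least squares on a
# shrinking smoothing parameter, Hunter-Lange style) followed by a vertex
# polish: the exact minimiser interpolates p observations, so the p
# smallest-residual points are interpolated and kept if they lower the loss.
# Inference is by seeded nonparametric case-resampling bootstrap. The
# likelihood-ratio-type test follows the check-loss ratio with a sparsity
# (1/density) estimate from a difference quotient of residual quantiles at
# the Hall-Sheather bandwidth.

#' Check (pinball) loss
#'
#' @param r residual vector.
#' @param tau quantile level in (0, 1).
#' @return `sum(r * (tau - (r < 0)))`.
#' @export
check_loss <- function(r, tau = 0.5) sum(r * (tau - (r < 0)))

# Core fitter on a design matrix (intercept already included if wanted).
rq_fit <- function(X, y, tau = 0.5, max_iter = 200L, tol = 1e-12) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop_rar(sprintf("rank-deficient design; dependent column(s): %s",
                     paste(dep, collapse = ", ")), "rar_collinearity_error")
  }
  b <- qr.coef(qrX, y)                      # least-squares start
  obj <- check_loss(y - X %*% b, tau)
  for (eps in 10^c(-2, -4, -6, -8)) {
    for (it in seq_len(max_iter)) {
      r <- drop(y - X %*% b)
      wt <- 1 / (eps + abs(r))
      A <- crossprod(X, X * wt)
      rhs <- crossprod(X, wt * y) + (2 * tau - 1) * colSums(X)
      b_new <- tryCatch(drop(solve(A, rhs)), error = function(e) b)
      obj_new <- check_loss(y - X %*% b_new, tau)
      moved <- max(abs(b_new - b))
      b <- b_new
      if (obj_new <= obj && obj - obj_new < tol * (1 + abs(obj)) &&
          moved < 1e-10) { obj <- obj_new; break }
      obj <- min(obj, obj_new)
    }
  }
  # Vertex polish: interpolate the p observations with smallest |residual|.
  r <- drop(y - X %*% b)
  idx <- order(abs(r))[seq_len(p)]
  bv <- tryCatch(drop(solve(X[idx, , drop = FALSE], y[idx])),
                 error = function(e) NULL)
  if (!is.null(bv) && all(is.finite(bv))) {
    objv <- check_loss(y - X %*% bv, tau)
    if (objv <= obj) { b <- bv; obj <- objv }
  }
  r <- drop(y - X %*% b)
  list(coefficients = stats::setNames(drop(b), colnames(X)),
       residuals = r, check_loss = obj, n = n, p = p, tau = tau)
}

# Build a numeric design matrix from a data frame of predictors; an empty
# frame yields the intercept-only design.
build_design <- function(design, intercept = TRUE) {
  design <- as.data.frame(design)
  X <- if (ncol(design)) stats::model.matrix(~ ., data = design)
       else matrix(1, nrow(design), 1L,
                   dimnames = list(NULL, "(Intercept)"))
  if (!intercept) X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  X
}

#' Quantile regression of PFS scores on RAR predictors
#'
#' Fits the conditional `tau`-quantile (default the median) of `outcome` on
#' the predictors in `design` (plus an intercept) by exact check-loss
#' minimisation. Rows with any missing value are dropped with a message.
#' Confidence intervals are percentile bootstrap over case resamples;
#' p-values use the normal approximation `2 * pnorm(-|est| / sd_boot)`.
#'
#' @param outcome numeric response vector (e.g. PFS Physical scores).
#' @param design data frame or matrix of predictors (covariates included by
#'   the caller); factors are expanded via `model.matrix`.
#' @param tau quantile level (default 0.5).
#' @param bootstrap_B bootstrap replicates (default 1000; 0 disables
#'   inference).
#' @param seed integer seed for the bootstrap.
#' @param ci_level confidence level (default 0.95).
#' @return a `quantreg_fit`: list with `tau`, `coefficients` data frame
#'   (`estimate`, `ci_lower`, `ci_upper`, `p_value`), `check_loss`,
#'   `residuals`, `n`, `n_dropped`, `seed`, plus the fitted design for
#'   nesting checks.
#' @export
median_regression <- function(outcome, design, tau = 0.5,
                              bootstrap_B = 1000L, seed = 1L,
                              ci_level = 0.95) {
  stopifnot(tau > 0, tau < 1)
  if (is.null(design))                      # intercept-only model
    design <- data.frame(row.names = seq_along(outcome))
  design <- as.data.frame(design)
  cc <- if (ncol(design)) stats::complete.cases(outcome, design)
        else !is.na(outcome)
  n_dropped <- sum(!cc)
  if (n_dropped > 0)
    message(sprintf("dropping %d incomplete case(s)", n_dropped))
  y <- outcome[cc]
  X <- build_design(design[cc, , drop = FALSE])
  if (length(y) <= ncol(X))
    stop_rar("fewer complete cases than coefficients", "rar_data_error")
  fit <- rq_fit(X, y, tau)
  coefs <- data.frame(
    term = colnames(X),
    estimate = unname(fit$coefficients),
    ci_lower = NA_real_, ci_upper = NA_real_, p_value = NA_real_,
    row.names = NULL
  )
  if (bootstrap_B > 0) {
    set.seed(seed)
    B <- matrix(NA_real_, bootstrap_B, ncol(X))
    for (b in seq_len(bootstrap_B)) {
      idx <- sample.int(length(y), replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      if (qr(Xb)$rank < ncol(Xb)) next     # degenerate resample: skip
      B[b, ] <- rq_fit(Xb, y[idx], tau)$coefficients
    }
    ok <- stats::complete.cases(B)
    a <- (1 - ci_level) / 2
    coefs$ci_lower <- apply(B[ok, , drop = FALSE], 2L, stats::quantile,
                            probs = a)
    coefs$ci_upper <- apply(B[ok, , drop = FALSE], 2L, stats::quantile,
                            probs = 1 - a)
    sds <- apply(B[ok, , drop = FALSE], 2L, stats::sd)
    coefs$p_value <- 2 * stats::pnorm(-abs(coefs$estimate) / sds)
  }
  structure(
    list(tau = tau, coefficients = coefs, check_loss = fit$check_loss,
         residuals = fit$residuals, n = length(y), n_dropped = n_dropped,
         seed = seed, X = X, y = y),
    class = "quantreg_fit"
  )
}

#' @export
print.quantreg_fit <- function(x, ...) {
  cat(sprintf("<quantreg_fit> tau=%.2f, n=%d, check loss=%.4f\n",
              x$tau, x$n, x$check_loss))
  print(x$coefficients, digits = 4)
  invisible(x)
}

# Hall-Sheather bandwidth for sparsity estimation at level tau.
hall_sheather_bandwidth <- function(n, tau, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  q <- stats::qnorm(tau)
  n^(-1 / 3) * z^(2 / 3) *
    ((1.5 * stats::dnorm(q)^2) / (2 * q^2 + 1))^(1 / 3)
}

#' Likelihood-ratio-type test for nested quantile regressions
#'
#' Check-loss ratio statistic
#' `2 * (loss_reduced - loss_full) / (tau * (1 - tau) * s)`, referred to a
#' chi-square with degrees of freedom equal to the number of extra columns.
#' The sparsity `s = 1/f(F^-1(tau))` is a difference quotient of sample
#' quantiles of the full-model residuals at the Hall-Sheather bandwidth,
#' after dropping the p residuals that are (numerically) zero at the fitted
#' vertex.
#'
#' @param full,reduced `quantreg_fit` objects on the same rows and `tau`;
#'   the reduced design's columns must be a subset of the full's.
#' @return list with `statistic`, `df`, `p_value`, `sparsity`, `bandwidth`.
#' @export
qr_likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "quantreg_fit"), inherits(reduced, "quantreg_fit"))
  if (full$tau != reduced$tau)
    stop_rar("models fitted at different tau", "rar_usage_error")
  if (full$n != reduced$n || !isTRUE(all.equal(full$y, reduced$y)))
    stop_rar("models fitted to different rows", "rar_usage_error")
  if (!all(colnames(reduced$X) %in% colnames(full$X)))
    stop_rar("designs are not nested", "rar_usage_error")
  df <- ncol(full$X) - ncol(reduced$X)
  tau <- full$tau
  if (df == 0L)
    return(list(statistic = 0, df = 0L, p_value = 1,
                sparsity = NA_real_, bandwidth = NA_real_))
  r <- full$residuals
  r <- r[rank(abs(r), ties.method = "first") > ncol(full$X)]  # drop vertex 0s
  h <- hall_sheather_bandwidth(length(r), tau)
  h <- min(h, tau - 1e-4, 1 - tau - 1e-4)
  qs <- stats::quantile(r, c(tau + h, tau - h), names = FALSE, type = 7)
  s <- (qs[1L] - qs[2L]) / (2 * h)
  if (!is.finite(s) || s <= 0) s <- .Machine$double.eps^0.5
  stat <- max(0, 2 * (reduced$check_loss - full$check_loss) /
                   (tau * (1 - tau) * s))
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       sparsity = s, bandwidth = h)
}
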