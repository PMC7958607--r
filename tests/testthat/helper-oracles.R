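# Independent oracles and fixture builders shared across test files.
# Oracles are deliberately written as direct transliterations of the
# definitions (slow, explicit) so they stay independent of the package's
# algorithmic routes.

# Brute-force non-wear oracle: enumerate candidate intervals [i, j] with
# zero endpoints, length >= w, total nonzero epochs <= a, and every nonzero
# burst inside flanked by >= s zeros (or an edge-touching zero run) on both
# sides; non-wear is the union of all qualifying intervals.
choi_oracle <- function(x, w = 90L, a = 2L, s = 30L) {
  n <- length(x)
  nz <- x != 0
  flank_ok <- function(i, j) {
    zb <- 0; k <- i - 1
    while (k >= 1 && !nz[k]) { zb <- zb + 1; k <- k - 1 }
    left <- (i - zb == 1) || zb >= s
    za <- 0; k <- j + 1
    while (k <= n && !nz[k]) { za <- za + 1; k <- k + 1 }
    right <- (j + za == n) || za >= s
    left && right
  }
  nonwear <- logical(n)
  for (i in seq_len(n)) {
    if (nz[i]) next
    cnt <- 0; j <- i
    while (j <= n) {
      if (nz[j]) {
        b0 <- j
        while (j < n && nz[j + 1]) j <- j + 1
        cnt <- cnt + (j - b0 + 1)
        if (cnt > a || !flank_ok(b0, j)) break
      } else if (j - i + 1 >= w) {
        nonwear[i:j] <- TRUE
      }
      j <- j + 1
    }
  }
  nonwear
}

# Random count vector mixing long zero runs with short activity bursts.
random_choi_vector <- function(n) {
  x <- integer(n)
  i <- 1
  while (i <= n) {
    if (stats::runif(1) < 0.5) {
      i <- i + sample(1:120, 1)
    } else {
      len <- sample(1:8, 1)
      hi <- min(n, i + len - 1)
      x[i:hi] <- sample(1:100, hi - i + 1, replace = TRUE)
      i <- hi + 1
    }
  }
  x
}

# Exhaustive vertex enumeration for quantile regression: the optimum
# interpolates p observations, so try every size-p subset.
rq_vertex_oracle <- function(X, y, tau = 0.5) {
  n <- nrow(X); p <- ncol(X)
  best <- Inf
  for (idx in utils::combn(n, p, simplify = FALSE)) {
    b <- tryCatch(solve(X[idx, , drop = FALSE], y[idx]),
                  error = function(e) NULL)
    if (is.null(b)) next
    best <- min(best, check_loss(y - X %*% b, tau))
  }
  best
}

# Exhaustive k-means optimum: all k^n assignments of n points (small n only).
kmeans_exhaustive_wss <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    g <- as.integer(grid[r, ])
    if (length(unique(g)) < k) next
    wss <- 0
    for (j in seq_len(k)) {
      pts <- x[g == j, , drop = FALSE]
      ctr <- colMeans(pts)
      wss <- wss + sum(sweep(pts, 2, ctr)^2)
    }
    best <- min(best, wss)
  }
  best
}

# Kruskal-Wallis H with tie correction, straight from the published formula.
kruskal_h_formula <- function(scores, groups) {
  r <- rank(scores)
  n <- length(scores)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  ties <- table(scores)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# A short synthetic series for I/O tests: deterministic given seed.
quick_series <- function(seed = 1, n_days = 2, epoch_seconds = 60,
                         id = "T01", noise_sd = 0.5) {
  set.seed(seed)
  cfg <- sim_config(n_participants = 1, n_days = n_days,
                    epoch_seconds = epoch_seconds, noise_sd = noise_sd,
                    seed = seed)
  p <- cosine_params(0.5, 5.9, -0.3, 22, 14.8)
  simulate_epoch_series(p, cfg, participant_id = id)
}

expect_hours_equal <- function(a, b, tol = 1e-6) {
  d <- abs((a - b + 12) %% 24 - 12)
  expect_lt(max(d), tol)
}
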