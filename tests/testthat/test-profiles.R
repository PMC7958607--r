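# Feature standardization, k-means, diagnostics, semantic labels.

fake_features <- function(n, p = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p)
  colnames(m) <- RAR_FEATURES_TEST
  rownames(m) <- sprintf("P%03d", seq_len(n))
  m
}
RAR_FEATURES_TEST <- c("alpha", "beta", "acrophase", "amplitude", "mesor",
                       "up_mesor", "down_mesor", "pseudo_f")

test_that("standardize_features z-scores, inverts, and flags degeneracy", {
  x <- fake_features(20)
  z <- standardize_features(x)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-10)
  # idempotent up to numerics
  z2 <- standardize_features(z)
  expect_lt(max(abs(z2 - z)), 1e-12)
  # round-trip inverse
  back <- sweep(sweep(z, 2, attr(z, "scale"), "*"), 2, attr(z, "center"), "+")
  expect_equal(back, x, ignore_attr = TRUE)
  # two participants become +/- x with mean zero
  z3 <- standardize_features(x[1:2, ])
  expect_equal(unname(z3[1, ]), -unname(z3[2, ]))
  # zero-variance column named in the error
  bad <- x; bad[, "mesor"] <- 3
  expect_error(standardize_features(bad), "mesor",
               class = "rar_degenerate_feature_error")
})

test_that("kmeans_fit separates blobs and honours boundary cases", {
  set.seed(5)
  blob <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
                matrix(rnorm(40, 8, 0.3), 20, 2))
  colnames(blob) <- c("a", "b")
  fit <- kmeans_fit(blob, k = 2, n_restarts = 10, seed = 3)
  expect_length(unique(fit$assignments[1:20]), 1L)
  expect_length(unique(fit$assignments[21:40]), 1L)
  expect_false(fit$assignments[1] == fit$assignments[40])
  # k = n gives zero within-SS
  small <- fake_features(5)
  expect_equal(kmeans_fit(small, k = 5, n_restarts = 5, seed = 1)$within_ss, 0)
  expect_error(kmeans_fit(small, k = 6, seed = 1), class = "rar_config_error")
  # within_ss equals the sum of squared distances to own centroid
  f2 <- kmeans_fit(small, k = 2, n_restarts = 10, seed = 2)
  d <- small - f2$centroids[f2$assignments, , drop = FALSE]
  expect_equal(f2$within_ss, sum(d^2))
})

test_that("best-of-restarts matches exhaustive enumeration on tiny instances", {
  set.seed(17)
  for (trial in 1:6) {
    n <- sample(6:7, 1)
    x <- matrix(rnorm(n), n, 1)
    colnames(x) <- "v"
    k <- sample(2:3, 1)
    fit <- kmeans_fit(x, k = k, n_restarts = 60, seed = trial)
    expect_equal(fit$within_ss, kmeans_exhaustive_wss(x, k),
                 tolerance = 1e-8, label = sprintf("trial %d", trial))
  }
})

test_that("assignments are invariant to feature column order", {
  x <- standardize_features(fake_features(30, seed = 4))
  f1 <- kmeans_fit(x, 3, n_restarts = 30, seed = 11)
  f2 <- kmeans_fit(x[, rev(colnames(x))], 3, n_restarts = 30, seed = 11)
  expect_equal(adjusted_rand_index(f1$assignments, f2$assignments), 1)
})

test_that("diagnostics report elbow, PCA and Ward summaries coherently", {
  x <- standardize_features(fake_features(25, seed = 8))
  d <- cluster_diagnostics(x, k_range = 1:6, n_restarts = 10, seed = 2)
  expect_true(all(diff(d$within_ss) <= 1e-8))       # non-increasing in k
  expect_equal(d$pca_cum_variance[length(d$pca_cum_variance)], 100)
  expect_length(d$ward_heights, 24L)                 # n - 1 merges
  expect_identical(dim(d$pc_scores), c(25L, 2L))
  # k = 1 within-SS is the total centred sum of squares
  expect_equal(d$within_ss[1L], sum(scale(x, scale = FALSE)^2))
})

test_that("label_clusters matches the qualitative profile signatures", {
  # centroids built to the published signatures (standardized units)
  ctr <- rbind(
    c(alpha =  1.0, beta =  0.8, acrophase = -0.8, amplitude = -0.9,
      mesor = -0.8, up_mesor = 0.2, down_mesor = -1.0, pseudo_f = -0.8),
    c(alpha = -0.2, beta = -0.2, acrophase = -0.2, amplitude = 0.0,
      mesor =  0.0, up_mesor = -0.7, down_mesor = 0.0, pseudo_f = 0.0),
    c(alpha = -0.3, beta = -0.3, acrophase =  0.2, amplitude = 1.1,
      mesor =  1.0, up_mesor = 0.0, down_mesor = 0.2, pseudo_f = 1.2),
    c(alpha =  0.0, beta =  0.0, acrophase =  1.2, amplitude = 0.0,
      mesor =  0.0, up_mesor = 1.3, down_mesor = 1.1, pseudo_f = 0.0)
  )
  model <- structure(list(k = 4L, centroids = ctr,
                          assignments = stats::setNames(rep(1:4, 3),
                                                        sprintf("P%02d", 1:12)),
                          within_ss = 1, seed = 1, labels = NULL),
                     class = "rar_cluster_model")
  out <- label_clusters(model)
  expect_identical(out$labels,
                   c("Less Active/Robust", "Earlier Risers",
                     "More Active/Robust", "Later RAR"))
  # permuting cluster ids permutes labels consistently
  perm <- c(3L, 1L, 4L, 2L)
  model2 <- model
  model2$centroids <- ctr[order(perm), ]
  out2 <- label_clusters(model2)
  expect_identical(out2$labels[perm], out$labels)
  # k != 4 leaves labels empty with a warning
  model3 <- model; model3$k <- 3L
  expect_warning(out3 <- label_clusters(model3), "k = 4")
  expect_null(out3$labels)
})

test_that("adjusted_rand_index matches a hand-computed case", {
  a <- c(1, 1, 1, 2, 2, 2)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(2, 2, 2, 1, 1, 1)), 1)  # relabelling
  b <- c(1, 1, 2, 2, 2, 2)
  # contingency 2x2: rows {3,3}, cols {2,4}; sum_ij C(n_ij,2) = 1+0+1+6(=C(4,2)... )
  # direct from the definition: (sum_ij - E) / (max - E)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2)); sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  e <- sum_a * sum_b / choose(6, 2)
  expect_equal(adjusted_rand_index(a, b),
               (sum_ij - e) / ((sum_a + sum_b) / 2 - e))
})
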