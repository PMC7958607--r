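# RAR profiling: standardize the eight fitted rhythm features, cluster
# participants with k-means (Lloyd iterations, k-means++ style seeding,
# best of many restarts), run cluster-count diagnostics, and attach the four
# semantic profile labels by centroid signature.

RAR_FEATURES <- c("alpha", "beta", "acrophase", "amplitude", "mesor",
                  "up_mesor", "down_mesor", "pseudo_f")

#' Feature matrix of fitted RAR parameters
#'
#' Extracts the eight clustering features from a fit table
#' ([rar_parameter_table()]): alpha, beta, acrophase, amplitude, mesor
#' (log scale), up mesor, down mesor, pseudo-F. Participants with
#' non-converged fits are excluded.
#'
#' @param fit_table data frame from [rar_parameter_table()].
#' @param log_beta cluster on `log(beta)` instead of raw beta (default FALSE,
#'   matching how beta is conventionally reported).
#' @return numeric matrix, rownames = participant ids.
#' @export
build_feature_matrix <- function(fit_table, log_beta = FALSE) {
  keep <- fit_table$converged
  ft <- fit_table[keep, , drop = FALSE]
  m <- cbind(
    alpha = ft$alpha,
    beta = if (log_beta) log(ft$beta) else ft$beta,
    acrophase = ft$phi,
    amplitude = ft$amp,
    mesor = ft$mesor_log,
    up_mesor = ft$up_mesor,
    down_mesor = ft$down_mesor,
    pseudo_f = ft$pseudo_f
  )
  rownames(m) <- ft$participant_id
  m
}

#' Column-wise z-scoring
#'
#' Standardizes each feature with its sample mean and SD (n - 1); the
#' centering/scaling constants are attached so the transform can be inverted.
#'
#' @param raw numeric matrix or data frame, no missing values, >= 2 rows.
#' @return standardized matrix with attributes `center`, `scale` and
#'   `standardized = TRUE`.
#' @export
standardize_features <- function(raw) {
  x <- as.matrix(raw)
  if (nrow(x) < 2L)
    stop_rar("need at least two participants to standardize",
             "rar_usage_error")
  if (anyNA(x))
    stop_rar("feature matrix contains missing values", "rar_data_error")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  zero <- scl == 0
  if (any(zero))
    stop_rar(sprintf("zero-variance feature column(s): %s",
                     paste(colnames(x)[zero], collapse = ", ")),
             "rar_degenerate_feature_error")
  z <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  attr(z, "standardized") <- TRUE
  z
}

# Squared Euclidean distances from each row of x to each row of centers.
sqdist_to_centers <- function(x, centers) {
  outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
}

# One Lloyd run from given initial centers; empty clusters are re-seeded
# from the point farthest from its assigned center.
lloyd_once <- function(x, centers, iter_max = 100L) {
  n <- nrow(x)
  assign_old <- rep(0L, n)
  for (it in seq_len(iter_max)) {
    d2 <- sqdist_to_centers(x, centers)
    assign_new <- max.col(-d2, ties.method = "first")
    for (j in seq_len(nrow(centers))) {
      if (!any(assign_new == j)) {
        far <- which.max(d2[cbind(seq_len(n), assign_new)])
        centers[j, ] <- x[far, ]
        assign_new[far] <- j
      }
    }
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    for (j in seq_len(nrow(centers)))
      centers[j, ] <- colMeans(x[assign_new == j, , drop = FALSE])
  }
  d2 <- sqdist_to_centers(x, centers)
  wss <- sum(pmax(d2[cbind(seq_len(n), assign_old)], 0))
  list(centers = centers, assignments = assign_old, within_ss = wss)
}

# k-means++ style seeding: first center uniform, then proportional to
# squared distance to the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[idx[1L], ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[j] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[idx[j], ])^2))
  }
  x[idx, , drop = FALSE]
}

#' K-means clustering of standardized RAR features
#'
#' Lloyd iterations from k-means++ style seeded starts; the restart with
#' the lowest within-cluster sum of squares is kept. Deterministic given
#' `seed`.
#'
#' @param features standardized feature matrix ([standardize_features()]).
#' @param k number of clusters (default 4).
#' @param n_restarts number of seeded restarts (default 100).
#' @param seed integer seed.
#' @return a `rar_cluster_model`: list with `k`, `centroids` (k x p,
#'   standardized units), `assignments` (named integer vector), `within_ss`,
#'   `seed`, `labels` (filled by [label_clusters()]).
#' @export
kmeans_fit <- function(features, k = 4L, n_restarts = 100L, seed = 1L) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (k < 1L || k > n)
    stop_rar("k must lie between 1 and the number of participants",
             "rar_config_error")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- lloyd_once(x, kmeanspp_centers(x, k))
    if (is.null(best) || fit$within_ss < best$within_ss - 1e-12) best <- fit
  }
  names(best$assignments) <- rownames(x)
  structure(
    list(k = k, centroids = best$centers, assignments = best$assignments,
         within_ss = best$within_ss, seed = seed, labels = NULL,
         features = colnames(x)),
    class = "rar_cluster_model"
  )
}

#' @export
print.rar_cluster_model <- function(x, ...) {
  cat(sprintf("<rar_cluster_model> k=%d, n=%d, within_ss=%.3f\n",
              x$k, length(x$assignments), x$within_ss))
  if (!is.null(x$labels))
    cat("  labels:", paste(sprintf("%d=%s", seq_along(x$labels), x$labels),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Cluster-count diagnostics
#'
#' The standard battery for choosing k: the within-sum-of-squares curve over
#' a range of k (elbow data), PCA eigenvalues with cumulative variance
#' explained, Ward-linkage agglomeration merge heights (Euclidean distance),
#' and participant coordinates on the first two principal components.
#'
#' @param features standardized feature matrix.
#' @param k_range integer vector of cluster counts (default 1:10).
#' @param n_restarts restarts per k (default 25).
#' @param seed integer seed.
#' @return a `rar_cluster_diagnostics` list: `k_range`, `within_ss`,
#'   `pca_eigenvalues`, `pca_cum_variance` (percent), `ward_heights`,
#'   `pc_scores` (n x 2).
#' @export
cluster_diagnostics <- function(features, k_range = 1:10, n_restarts = 25L,
                                seed = 1L) {
  x <- as.matrix(features)
  k_range <- k_range[k_range <= nrow(x)]
  wss <- vapply(seq_along(k_range), function(i) {
    kmeans_fit(x, k_range[i], n_restarts,
               seed = derive_seed(seed, i))$within_ss
  }, numeric(1))
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  structure(
    list(k_range = k_range,
         within_ss = wss,
         pca_eigenvalues = ev,
         pca_cum_variance = 100 * cumsum(ev) / sum(ev),
         ward_heights = hc$height,
         pc_scores = pca$x[, 1:2, drop = FALSE]),
    class = "rar_cluster_diagnostics"
  )
}

RAR_PROFILE_LABELS <- c("Less Active/Robust", "Earlier Risers",
                        "More Active/Robust", "Later RAR")

#' Assign semantic profile labels to four clusters
#'
#' Deterministic signature matching on standardized centroids: "Later RAR"
#' is the cluster with the largest mean z of the timing features (up mesor,
#' acrophase, down mesor); among the rest, "More Active/Robust" has the
#' largest and "Less Active/Robust" the smallest mean z of the
#' magnitude/robustness features (amplitude, mesor, pseudo-F); the remaining
#' cluster is "Earlier Risers". Ties break by cluster id. With `k != 4`
#' labels are left empty with a warning (the clustering itself stays valid).
#'
#' @param model a `rar_cluster_model`.
#' @return the model with `labels` populated (cluster id -> label).
#' @export
label_clusters <- function(model) {
  stopifnot(inherits(model, "rar_cluster_model"))
  if (model$k != 4L) {
    warning("profile labels are defined for k = 4 only; labels left empty")
    return(model)
  }
  ctr <- model$centroids
  timing <- rowMeans(ctr[, c("up_mesor", "acrophase", "down_mesor"),
                         drop = FALSE])
  act <- rowMeans(ctr[, c("amplitude", "mesor", "pseudo_f"), drop = FALSE])
  labels <- character(4L)
  later <- which.max(timing)
  labels[later] <- "Later RAR"
  rest <- setdiff(1:4, later)
  more <- rest[which.max(act[rest])]
  labels[more] <- "More Active/Robust"
  rest <- setdiff(rest, more)
  less <- rest[which.min(act[rest])]
  labels[less] <- "Less Active/Robust"
  labels[setdiff(rest, less)] <- "Earlier Risers"
  model$labels <- labels
  model
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement, used to score cluster recovery against
#' ground-truth archetype labels on synthetic cohorts.
#'
#' @param a,b partition vectors of equal length.
#' @return ARI in [-1, 1]; 1 = identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
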