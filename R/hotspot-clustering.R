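# Hotspot detection: Gaussian-mixture fits, Calinski-Harabasz model
# selection, Mahalanobis outlier exclusion, per-cluster composition.

# log N(x | mu, Sigma) for 2D points, vectorized over rows of X
log_dmvnorm2 <- function(X, mu, Sigma) {
  R <- chol(Sigma)
  logdet <- 2 * sum(log(diag(R)))
  Z <- backsolve(R, t(X) - mu, transpose = TRUE)
  -0.5 * colSums(Z^2) - 0.5 * logdet - log(2 * pi)
}

# k-means++ seeding of K initial means
kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- X[sample.int(n, 1), , drop = FALSE]
  while (nrow(centers) < K) {
    d2 <- rep(Inf, n)
    for (j in seq_len(nrow(centers)))
      d2 <- pmin(d2, (X[, 1] - centers[j, 1])^2 +
                   (X[, 2] - centers[j, 2])^2)
    if (sum(d2) == 0) {
      idx <- sample.int(n, 1)
    } else {
      idx <- sample.int(n, 1, prob = d2)
    }
    centers <- rbind(centers, X[idx, , drop = FALSE])
  }
  centers
}

run_em <- function(X, K, reg, max_iter, tol) {
  n <- nrow(X)
  mu <- kmeanspp_init(X, K)
  S0 <- stats::cov(X) + reg * diag(2)
  Sigma <- replicate(K, S0, simplify = FALSE)
  w <- rep(1 / K, K)
  ll_old <- -Inf
  resp <- NULL
  for (iter in seq_len(max_iter)) {
    logd <- matrix(0, n, K)
    for (k in seq_len(K))
      logd[, k] <- log(w[k]) + log_dmvnorm2(X, mu[k, ], Sigma[[k]])
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    resp <- exp(logd - lse)
    Nk <- colSums(resp)
    if (any(Nk < 1e-6)) return(NULL)      # degenerate collapse
    w <- Nk / n
    for (k in seq_len(K)) {
      mu[k, ] <- colSums(resp[, k] * X) / Nk[k]
      Xc <- sweep(X, 2, mu[k, ])
      S <- crossprod(sqrt(resp[, k]) * Xc) / Nk[k] + reg * diag(2)
      ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
      if (!ok) return(NULL)
      Sigma[[k]] <- S
    }
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(weights = w, means = mu, covariances = Sigma,
       log_likelihood = ll, responsibilities = resp)
}

#' Fit a K-component Gaussian mixture to x-y synapse coordinates
#'
#' Full-covariance EM, best of `n_restarts` k-means++-seeded runs by
#' log-likelihood; deterministic given `seed`. Covariances carry a
#' trace-scaled diagonal ridge of 1e-6 so the fit cannot collapse onto a
#' single point. Hard assignments are the argmax responsibility per point.
#'
#' @param points two-column matrix/data.frame of x-y coordinates (um).
#' @param K number of components (>= 1; requires `nrow(points) >= 2 K`).
#' @param n_restarts EM restarts (default 10).
#' @param seed integer RNG seed.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return A `cluster_model`: `K`, `weights`, `means` (K x 2),
#'   `covariances` (list of 2 x 2), `log_likelihood`, `assignments`,
#'   `responsibilities`, `ch_index` (NA for K = 1 or empty hard clusters),
#'   `seed`.
#' @export
fit_gmm <- function(points, K, n_restarts = 10, seed, max_iter = 500,
                    tol = 1e-8) {
  X <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (K < 1) stop("K must be >= 1")
  if (n < 2 * K)
    stop("insufficient data: need at least 2K points (n = ", n,
         ", K = ", K, ")")
  reg <- 1e-6 * sum(diag(stats::cov(X))) / 2
  if (!is.finite(reg) || reg <= 0) reg <- 1e-6
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      fit <- run_em(X, K, reg, max_iter, tol)
      if (is.null(fit)) next
      if (is.null(best) || fit$log_likelihood > best$log_likelihood)
        best <- fit
    }
  })
  if (is.null(best))
    stop("EM failed for all ", n_restarts, " restarts (degenerate fits)")
  assignments <- max.col(best$responsibilities, ties.method = "first")
  ch <- NA_real_
  if (K >= 2 && length(unique(assignments)) == K && n > K)
    ch <- ch_index(X, assignments)
  structure(list(K = as.integer(K), weights = best$weights,
                 means = best$means, covariances = best$covariances,
                 log_likelihood = best$log_likelihood,
                 assignments = assignments,
                 responsibilities = best$responsibilities,
                 ch_index = ch, seed = as.integer(seed)),
            class = "cluster_model")
}

#' Calinski-Harabasz index of a hard partition
#'
#' CH = \[sum_k n_k ||c_k - c||^2 / (K - 1)\] /
#' \[sum_k sum_i ||d_i - c_k||^2 / (N - K)\], where c is the global
#' centroid and c_k, n_k the centroid and size of cluster k. Scale
#' invariant; larger is better. Zero within-cluster dispersion returns
#' +Inf with a warning.
#'
#' @param points two-column matrix of x-y coordinates.
#' @param labels integer cluster labels in 1..K, every cluster non-empty.
#' @param centroids optional K x 2 matrix of cluster centroids; defaults to
#'   the per-label means (the partition centroids of the definition).
#' @return The CH index (numeric scalar).
#' @export
ch_index <- function(points, labels, centroids = NULL) {
  X <- as.matrix(points)[, 1:2, drop = FALSE]
  labels <- as.integer(labels)
  N <- nrow(X)
  ks <- sort(unique(labels))
  K <- length(ks)
  if (K < 2) stop("need K >= 2 clusters")
  if (N <= K) stop("need N > K points")
  if (!all(seq_len(K) %in% ks)) {
    # relabel to 1..K preserving order
    labels <- match(labels, ks)
  }
  nk <- tabulate(labels, K)
  if (any(nk == 0)) stop("empty cluster")
  if (is.null(centroids)) {
    centroids <- matrix(0, K, 2)
    for (k in seq_len(K))
      centroids[k, ] <- colMeans(X[labels == k, , drop = FALSE])
  }
  g <- colMeans(X)
  between <- sum(nk * rowSums(sweep(centroids, 2, g)^2)) / (K - 1)
  within <- sum((X - centroids[labels, , drop = FALSE])^2) / (N - K)
  if (within == 0) {
    warning("zero within-cluster dispersion; CH index is +Inf")
    return(Inf)
  }
  between / within
}

#' Select the number of hotspot components by the CH index
#'
#' Fits Gaussian mixtures for K = `k_min`..`k_max`, scores the hard
#' assignments with the CH index, and returns the model with the largest
#' CH (ties broken toward smaller K, for parsimony). K values whose fit
#' failed or produced an empty hard cluster are skipped and recorded. A
#' CH curve whose maximum is below twice its median is flagged low
#' contrast: no pronounced interior optimum, as for a single homogeneous
#' blob.
#'
#' @param points two-column matrix/data.frame of x-y coordinates.
#' @param k_min,k_max component range (default 2..10).
#' @param n_restarts EM restarts per K.
#' @param seed integer RNG seed.
#' @return list with `model` (best `cluster_model`), `ch_by_k`
#'   (data.frame K/ch/log_likelihood/status), `low_contrast` flag.
#' @export
select_components <- function(points, k_min = 2, k_max = 10,
                              n_restarts = 10, seed) {
  X <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(X) < 2 * k_min)
    stop("insufficient data for k_min = ", k_min)
  ks <- seq.int(k_min, k_max)
  models <- vector("list", length(ks))
  tab <- data.frame(K = ks, ch = NA_real_, log_likelihood = NA_real_,
                    status = "ok", stringsAsFactors = FALSE)
  for (i in seq_along(ks)) {
    K <- ks[i]
    fit <- tryCatch(fit_gmm(X, K, n_restarts = n_restarts, seed = seed),
                    error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      tab$status[i] <- fit
      next
    }
    models[[i]] <- fit
    tab$log_likelihood[i] <- fit$log_likelihood
    if (is.na(fit$ch_index)) {
      tab$status[i] <- "empty hard cluster"
    } else {
      tab$ch[i] <- fit$ch_index
    }
  }
  ok <- which(is.finite(tab$ch))
  if (!length(ok)) stop("all mixture fits failed across K = ",
                        k_min, "..", k_max)
  best_i <- ok[which.max(tab$ch[ok])]   # which.max takes the first: low K
  low_contrast <- max(tab$ch[ok]) < 2 * stats::median(tab$ch[ok])
  list(model = models[[best_i]], ch_by_k = tab,
       low_contrast = low_contrast)
}

#' Mahalanobis distance of points from a mixture component
#'
#' d = sqrt((x - mu) Sigma^-1 (x - mu)'), the distance from the component
#' mean in standard deviations.
#'
#' @param x a point (length-2) or two-column matrix of points.
#' @param mean component mean (length 2).
#' @param cov 2 x 2 positive-definite covariance.
#' @return Distance(s) in SD units.
#' @export
mahalanobis_distance <- function(x, mean, cov) {
  X <- if (is.null(dim(x))) matrix(x, ncol = 2) else as.matrix(x)
  ok <- tryCatch({ chol(cov); TRUE }, error = function(e) FALSE)
  if (!ok) stop("singular covariance")
  sqrt(stats::mahalanobis(X, center = mean, cov = cov))
}

#' Flag synapses beyond a Mahalanobis threshold of every cluster
#'
#' A point is an outlier only if its distance exceeds `threshold` SDs for
#' all components: points inside any cluster's bound are kept.
#'
#' @param points two-column matrix of x-y coordinates.
#' @param model a `cluster_model`.
#' @param threshold SD bound (default 3, the published exclusion rule).
#' @return Logical mask, TRUE = outlier.
#' @export
flag_outliers <- function(points, model, threshold = 3) {
  X <- as.matrix(points)[, 1:2, drop = FALSE]
  dmin <- rep(Inf, nrow(X))
  for (k in seq_len(model$K))
    dmin <- pmin(dmin, mahalanobis_distance(X, model$means[k, ],
                                            model$covariances[[k]]))
  dmin > threshold
}

#' Per-cluster composition of presynaptic types
#'
#' Proportions of each presynaptic bipolar type among the non-outlier
#' members of each cluster; proportions within a cluster sum to 1. Clusters
#' emptied by outlier removal are reported as empty.
#'
#' @param synapses ribbon synapse records with a `pre_type` column, one row
#'   per point used to fit `model` (same order).
#' @param model a `cluster_model`.
#' @param outliers logical mask as from [flag_outliers()]; default none.
#' @return Named list (cluster_1..cluster_K) of named proportion vectors.
#' @export
cluster_composition <- function(synapses, model, outliers = NULL) {
  if (is.null(outliers)) outliers <- rep(FALSE, nrow(synapses))
  stopifnot(nrow(synapses) == length(model$assignments),
            length(outliers) == nrow(synapses))
  out <- list()
  for (k in seq_len(model$K)) {
    members <- synapses$pre_type[model$assignments == k & !outliers]
    out[[paste0("cluster_", k)]] <-
      if (!length(members)) numeric(0) else
        prop.table(table(members))
  }
  out
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> K = %d, logLik = %.2f, CH = %s\n",
              x$K, x$log_likelihood,
              ifelse(is.na(x$ch_index), "NA",
                     sprintf("%.2f", x$ch_index))))
  for (k in seq_len(x$K))
    cat(sprintf("  %d: weight %.3f, mean (%.1f, %.1f), sd (%.1f, %.1f)\n",
                k, x$weights[k], x$means[k, 1], x$means[k, 2],
                sqrt(x$covariances[[k]][1, 1]),
                sqrt(x$covariances[[k]][2, 2])))
  invisible(x)
}
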