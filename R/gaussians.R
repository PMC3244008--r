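# Shared multivariate-Gaussian and mixture machinery (used by the
# probabilistic single-frame classifiers and by the HMM emissions).

# Regularise a covariance estimate: floor 1e-6 * mean(diag) on the diagonal;
# if still not positive-definite (e.g. fewer instances than dimensions),
# shrink halfway towards its diagonal, escalating until a Cholesky exists.
regularize_cov <- function(S, n_obs = Inf) {
  d <- nrow(S)
  md <- mean(diag(S))
  if (!is.finite(md) || md <= 0) md <- 1
  S <- S + diag(1e-6 * md, d)
  shrink <- if (n_obs <= d) 0.5 else 0
  repeat {
    Sr <- (1 - shrink) * S + shrink * diag(diag(S), d)
    ok <- tryCatch({ chol(Sr); TRUE }, error = function(e) FALSE)
    if (ok) return(Sr)
    shrink <- if (shrink == 0) 0.5 else min(0.99, shrink + 0.2)
    if (shrink >= 0.99) {
      return(diag(pmax(diag(S), 1e-6 * md), d))
    }
  }
}

# log N(x | mean, cov) for rows of X
dmvnorm_log <- function(X, mean, cov) {
  X <- rbind(X)
  d <- ncol(X)
  L <- chol(cov)
  centred <- sweep(X, 2L, mean)
  z <- backsolve(L, t(centred), transpose = TRUE)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(L))) + colSums(z^2))
}

rmvnorm_chol <- function(n, mean, cov) {
  d <- length(mean)
  L <- chol(cov)
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% L, 2L, mean, `+`)
}

# Gaussian mixture container: list(weights, means (M x d), covariances
# (list of M d x d matrices))
new_gaussian_mixture <- function(weights, means, covariances) {
  means <- rbind(means)
  stopifnot(length(weights) == nrow(means),
            length(covariances) == nrow(means))
  w <- weights / sum(weights)
  structure(list(weights = w, means = means, covariances = covariances),
            class = "gaussian_mixture")
}

# log density of mixture for rows of X
gm_log_density <- function(mix, X) {
  X <- rbind(X)
  comp <- vapply(seq_along(mix$weights), function(m) {
    log(mix$weights[m]) + dmvnorm_log(X, mix$means[m, ], mix$covariances[[m]])
  }, numeric(nrow(X)))
  comp <- rbind(comp)
  apply(comp, 1L, logsumexp)
}

# per-component log joint densities (T x M), used by Baum-Welch mode = "all"
gm_component_log <- function(mix, X) {
  X <- rbind(X)
  out <- vapply(seq_along(mix$weights), function(m) {
    log(mix$weights[m]) + dmvnorm_log(X, mix$means[m, ], mix$covariances[[m]])
  }, numeric(nrow(X)))
  rbind(out)
}

# Fit an M-component Gaussian mixture. M = 1 is the closed-form
# mean/regularised-covariance estimate; M > 1 runs EM from a k-means
# partition obtained under a fixed seed.
fit_gaussian_mixture <- function(X, M = 1, seed = 1, max_iter = 100, tol = 1e-6) {
  X <- rbind(X)
  n <- nrow(X); d <- ncol(X)
  if (n < M + 1) stop(sprintf("need at least M + 1 = %d instances, got %d", M + 1, n),
                      call. = FALSE)
  if (M == 1) {
    mu <- colMeans(X)
    S <- if (n > 1) stats::cov(X) * (n - 1) / n else diag(1e-6, d)
    return(new_gaussian_mixture(1, matrix(mu, 1), list(regularize_cov(S, n))))
  }
  km <- with_seed_if(seed, stats::kmeans(X, centers = M, nstart = 1, iter.max = 50))
  assign <- km$cluster
  weights <- tabulate(assign, M) / n
  means <- km$centers
  covs <- lapply(seq_len(M), function(m) {
    Xi <- X[assign == m, , drop = FALSE]
    S <- if (nrow(Xi) > 1) stats::cov(Xi) * (nrow(Xi) - 1) / nrow(Xi) else
      diag(apply(X, 2, stats::var) + 1e-6, d)
    regularize_cov(S, nrow(Xi))
  })
  mix <- new_gaussian_mixture(weights, means, covs)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    comp <- gm_component_log(mix, X)            # n x M
    ll_rows <- apply(comp, 1L, logsumexp)
    ll <- sum(ll_rows)
    resp <- exp(comp - ll_rows)                 # responsibilities
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-10)
    means <- t(resp) %*% X / nk
    covs <- lapply(seq_len(M), function(m) {
      centred <- sweep(X, 2L, means[m, ])
      S <- t(centred * resp[, m]) %*% centred / nk[m]
      regularize_cov(S, nk[m])
    })
    mix <- new_gaussian_mixture(nk / n, means, covs)
    if (is.finite(ll_prev) && (ll - ll_prev) < tol * abs(ll_prev)) break
    ll_prev <- ll
  }
  mix
}

# Class-conditional Gaussian (mixture) fits shared by the single-frame GMM
# classifier and the cHMM emissions. For M = 1 the per-class covariance is
# shrunk towards the pooled within-class covariance (regularised
# discriminant analysis) with weight gamma = d / (d + n_c), which vanishes
# as the class sample grows and dominates when n_c < d; without it,
# few-sample covariances collapse in unsampled directions and their
# log-determinants swamp the decision rule.
fit_class_gaussians <- function(X, labels, classes, M = 1, seed = 1) {
  d <- ncol(X)
  by_class <- lapply(classes, function(cl) X[labels == cl, , drop = FALSE])
  names(by_class) <- classes
  for (cl in classes) {
    if (nrow(by_class[[cl]]) < M + 1) {
      stop(sprintf("class '%s' has %d frames; need at least M + 1 = %d",
                   cl, nrow(by_class[[cl]]), M + 1), call. = FALSE)
    }
  }
  if (M > 1) {
    return(lapply(by_class, fit_gaussian_mixture, M = M, seed = seed))
  }
  pooled <- Reduce(`+`, lapply(by_class, function(Xc) {
    crossprod(sweep(Xc, 2L, colMeans(Xc)))
  })) / max(nrow(X) - length(classes), 1L)
  floor_term <- diag(1e-6 * max(mean(diag(pooled)), 1e-12), d)
  lapply(by_class, function(Xc) {
    n_c <- nrow(Xc)
    mu <- colMeans(Xc)
    S <- crossprod(sweep(Xc, 2L, mu)) / n_c
    gamma <- d / (d + n_c)
    new_gaussian_mixture(1, matrix(mu, 1, dimnames = list(NULL, colnames(X))),
                         list((1 - gamma) * S + gamma * pooled + floor_term))
  })
}
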