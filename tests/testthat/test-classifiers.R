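test_that("single-Gaussian class models store exact sample means", {
  d <- toy_classes(n_per = 10, d = 3, seed = 4)
  m <- fit_probabilistic(d, "gmm", M = 1)
  for (cl in c("a", "b")) {
    expect_equal(unname(m$models[[cl]]$means[1, ]),
                 unname(colMeans(feature_matrix(d[d$label == cl, ]))))
  }
})

test_that("fitted class means recover well-separated 1-d Gaussians", {
  withr::with_seed(0, {
    d <- tibble::tibble(label = rep(c("c1", "c2"), each = 500),
                        f = c(rnorm(500, 0), rnorm(500, 4)))
  })
  m <- fit_probabilistic(d, "gmm")
  expect_equal(unname(m$models$c1$means[1, 1]), 0, tolerance = 0.2)
  expect_equal(unname(m$models$c2$means[1, 1]), 4, tolerance = 0.2)
  # hand-computed Gaussian densities at x = 1: dnorm(1,0,1) = 0.2420 wins
  # over dnorm(1,4,1) = 0.0044
  expect_identical(unname(classify_probabilistic(m, c(f = 1))), "c1")
})

test_that("maximum-likelihood rule breaks ties towards the lower class index", {
  m <- fit_probabilistic(
    tibble::tibble(label = rep(c("a", "b"), each = 3),
                   f = c(-1, 0, 1, 3, 4, 5)), "gmm")
  # x = 2 is the exact midpoint of two symmetric classes
  expect_identical(unname(classify_probabilistic(m, c(f = 2))), "a")
})

test_that("parzen density peaks at a lone training point", {
  d <- tibble::tibble(label = c("a", "b", "b"), f1 = c(2, 8, 9), f2 = c(1, 7, 8))
  m <- fit_probabilistic(d, "parzen")
  at_point <- predict(m, rbind(c(f1 = 2, f2 = 1)), type = "score")[, "a"]
  nearby <- predict(m, rbind(c(f1 = 2.5, f2 = 1.5)), type = "score")[, "a"]
  expect_gt(at_point, nearby)
})

test_that("geometric classifiers follow centroids and neighbour majorities", {
  d <- tibble::tibble(label = rep(c("a", "b"), each = 4),
                      f = c(-0.1, 0, 0.1, 0, 9.9, 10, 10.1, 10))
  nm <- fit_geometric(d, "nearest_mean")
  expect_identical(unname(classify_geometric(nm, c(f = 1))), "a")

  d3 <- tibble::tibble(label = c("A", "A", "B", "B"), f = c(1, 1.2, 2, 50))
  kn1 <- fit_geometric(d3, "knn", k = 1)
  expect_identical(unname(classify_geometric(kn1, c(f = 1.9))), "B")
  kn3 <- fit_geometric(d3, "knn", k = 3)
  # neighbours of 1.5 at k = 3 are labelled {A, A, B} -> majority A
  expect_identical(unname(classify_geometric(kn3, c(f = 1.5))), "A")
})

test_that("k = n nearest neighbours reduce to the majority class", {
  d <- tibble::tibble(label = c(rep("maj", 6), rep("min", 3)),
                      f1 = rnorm(9), f2 = rnorm(9))
  m <- fit_geometric(d, "knn", k = 9)
  expect_true(all(predict(m, d) == "maj"))
})

test_that("shared-covariance Gaussian rule equals Mahalanobis nearest mean", {
  withr::with_seed(7, {
    d <- toy_classes(n_per = 25, d = 3, gap = 2, seed = 7)
    m <- fit_probabilistic(d, "gmm")
    S <- m$models$a$covariances[[1]]
    m$models$b$covariances[[1]] <- S     # impose a shared covariance
    Sinv <- solve(S)
    X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("f", 1:3)))
    pred <- predict(m, X)
    # brute-force Mahalanobis distance to each class mean
    brute <- apply(X, 1, function(x) {
      dm <- vapply(m$models, function(mm) {
        v <- x - mm$means[1, ]
        sqrt(drop(v %*% Sinv %*% v))
      }, numeric(1))
      names(dm)[which.min(dm)]
    })
    expect_identical(unname(pred), unname(brute))
  })
})

test_that("prior weighting is available behind a flag", {
  d <- tibble::tibble(label = c(rep("a", 20), rep("b", 4)),
                      f = c(rnorm(20, 0, 1), rnorm(4, 2, 1)))
  m <- fit_probabilistic(d, "gmm")
  x <- c(f = 1.2)
  s0 <- predict(m, rbind(x), type = "score")
  s1 <- predict(m, rbind(x), type = "score", use_prior = TRUE)
  expect_equal(as.vector(s1 - s0), unname(log(m$priors)), tolerance = 1e-12)
})

test_that("dimension mismatches and degenerate training sets error", {
  d <- toy_classes(n_per = 5, d = 2)
  m <- fit_probabilistic(d, "gmm")
  expect_error(predict(m, matrix(0, 1, 5)), "dimension")
  expect_error(fit_probabilistic(tibble::tibble(label = c("a", "b"), f = c(1, 2)),
                                 "gmm"), "fewer than 2")
})

test_that("confusion matrices count, expose accuracy and aggregate", {
  cm <- confusion_matrix(c("a", "a", "b", "b"), c("a", "a", "b", "a"),
                         labels = c("a", "b"))
  expect_equal(accuracy(cm), 0.75)
  expect_equal(unname(rowSums(cm$counts)), c(2, 2))

  perfect <- confusion_matrix(c("a", "b"), c("a", "b"))
  expect_equal(accuracy(perfect), 1)

  agg <- aggregate_confusions(list(cm, cm))
  expect_equal(sum(agg$counts), 8)
  expect_identical(aggregate_confusions(list(cm))$counts, cm$counts)

  # aggregate accuracy is the outcome-weighted mean of member accuracies
  cm2 <- confusion_matrix(rep("a", 6), c(rep("a", 5), "b"), labels = c("a", "b"))
  agg2 <- aggregate_confusions(list(cm, cm2))
  expect_equal(accuracy(agg2),
               (accuracy(cm) * 4 + accuracy(cm2) * 6) / 10)

  cm3 <- confusion_matrix("x", "x")
  expect_error(aggregate_confusions(list(cm, cm3)), "label sets")
})

test_that("classifier evaluation fills a confusion matrix over test labels", {
  d <- toy_classes(n_per = 20, d = 2, gap = 8, seed = 5)
  m <- fit_geometric(d, "nearest_mean")
  cm <- evaluate_classifier(m, d)
  expect_s3_class(cm, "confusion_matrix")
  expect_equal(sum(cm$counts), nrow(d))
  expect_equal(accuracy(cm), 1)
})

test_that("the mixture EM agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  withr::with_seed(42, {
    X <- rbind(matrix(rnorm(120, 0), 60, 2), matrix(rnorm(120, 5), 60, 2))
  })
  ours <- actihmm:::fit_gaussian_mixture(X, M = 2, seed = 1)
  ll_ours <- sum(actihmm:::gm_log_density(ours, X))
  ref <- mclust::Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  expect_equal(ll_ours, ref$loglik, tolerance = 0.02)
  mu_ours <- ours$means[order(ours$means[, 1]), ]
  mu_ref <- t(ref$parameters$mean)[order(t(ref$parameters$mean)[, 1]), ]
  expect_equal(unname(mu_ours), unname(mu_ref), tolerance = 0.05)
})
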