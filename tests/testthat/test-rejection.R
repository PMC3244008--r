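test_that("frame scores follow the closed-form Gaussian density at a mode", {
  em <- list(actihmm:::new_gaussian_mixture(1, matrix(c(0, 0), 1), list(diag(2))),
             actihmm:::new_gaussian_mixture(1, matrix(c(9, 9), 1), list(diag(2))))
  # log N(mu | mu, I) in d = 2 is -log(2*pi)
  expect_equal(unname(frame_score(em, rbind(c(0, 0)))), -log(2 * pi),
               tolerance = 1e-12)
  # max over states is invariant to state order
  expect_equal(frame_score(em, rbind(c(3, 3))), frame_score(rev(em), rbind(c(3, 3))))
  # moving away from all means decreases the score
  ray <- t(sapply(seq(0, 40, by = 5), function(k) c(9 + k, 9 + k)))
  expect_true(all(diff(frame_score(em, ray)) < 0))
})

test_that("ROC calibration separates what is separable", {
  rej <- calibrate_threshold(inlier_scores = c(-3, -2, -1), outlier_scores = c(-9, -8))
  expect_equal(rej$sensitivity, 1)
  expect_equal(rej$specificity, 1)
  expect_gt(rej$threshold, -8)
  expect_lt(rej$threshold, -3)
  expect_equal(rejection_auc(rej), 1)
})

test_that("indistinguishable scores give a chance-level operating point", {
  withr::with_seed(0, {
    rej <- calibrate_threshold(rnorm(1000), rnorm(1000))
  })
  expect_equal(rej$sensitivity + rej$specificity, 1, tolerance = 0.15)
  expect_gte(rejection_auc(rej), 0)
  expect_lte(rejection_auc(rej), 1)
})

test_that("rejection masks are threshold-monotone and respect extremes", {
  em <- list(actihmm:::new_gaussian_mixture(1, matrix(c(0, 0), 1), list(diag(2))))
  X <- matrix(rnorm(40), 20, 2)
  base <- calibrate_threshold(c(-1), c(-2))
  none <- base; none$threshold <- -Inf
  all_ <- base; all_$threshold <- Inf
  expect_false(any(reject_spurious(none, em, X)))
  expect_true(all(reject_spurious(all_, em, X)))
  scores <- frame_score(em, X)
  masks <- lapply(sort(scores), function(t) {
    r <- base; r$threshold <- t
    reject_spurious(r, em, X)
  })
  for (i in seq_len(length(masks) - 1)) {
    expect_true(all(masks[[i + 1]] | !masks[[i]]))  # raising never un-rejects
  }
})

test_that("far-off garbage is rejected with high sensitivity and specificity", {
  withr::with_seed(0, {
    lib <- tiny_library(frames_per_class = 10, seed = 3)
    m <- first_phase_train(
      make_virtual_experiment(tiny_omm(), lib, 150, seed = 4),
      labels = tiny_omm()$labels)
    genuine <- make_virtual_experiment(tiny_omm(), lib, 200, seed = 5)
    X <- feature_matrix(genuine)
    garbage <- X[sample(nrow(X), 60), ] + 40   # >= 10 sd from every state mean
    cal_in <- frame_score(m, X[1:100, ])
    cal_out <- frame_score(m, garbage[1:30, ])
    rej <- calibrate_threshold(cal_in, cal_out)
    held_genuine <- frame_score(m, X[101:200, ])
    held_garbage <- frame_score(m, garbage[31:60, ])
    expect_gte(mean(held_garbage < rej$threshold), 0.95)
    expect_lte(mean(held_genuine < rej$threshold), 0.05)
  })
})

test_that("the ROC curve is a valid non-increasing step trade-off", {
  withr::with_seed(2, {
    rej <- calibrate_threshold(rnorm(200, 1), rnorm(200, -1))
  })
  ord <- order(rej$roc$threshold)
  expect_true(all(diff(rej$roc$sensitivity[ord]) >= 0))
  expect_true(all(diff(rej$roc$specificity[ord]) <= 0))
  expect_gte(rejection_auc(rej), 0.5)
})
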