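test_that("forward likelihood and Viterbi match exhaustive enumeration", {
  withr::with_seed(1, {
    for (i in 1:6) {
      Q <- sample(2:3, 1)
      Tn <- sample(2:6, 1)
      m <- random_chmm(Q = Q, d = 2, seed = 100 + i)
      X <- simulate_chmm(m, Tn, seed = 200 + i)$observations
      oracle <- brute_force_paths(m, X)
      expect_equal(forward_loglik(m, X), oracle$loglik, tolerance = 1e-8)
      vd <- viterbi_decode(m, X)
      expect_equal(vd$log_prob, oracle$best_logprob, tolerance = 1e-8)
      expect_identical(vd$path, oracle$best_path)
    }
  })
})

test_that("degenerate chains reduce to per-frame density sums", {
  m1 <- random_chmm(Q = 1, d = 2, seed = 3)
  X <- simulate_chmm(m1, 6, seed = 4)$observations
  expect_equal(forward_loglik(m1, X),
               sum(actihmm:::gm_log_density(m1$emissions[[1]], X)),
               tolerance = 1e-10)
  expect_identical(viterbi_decode(m1, X)$path, rep("s1", 6))

  m <- random_chmm(Q = 3, d = 2, seed = 5)
  x1 <- simulate_chmm(m, 1, seed = 6)$observations
  per_state <- vapply(seq_len(3), function(j)
    log(m$omm$prior[j]) + actihmm:::gm_log_density(m$emissions[[j]], x1),
    numeric(1))
  expect_equal(forward_loglik(m, x1), actihmm:::logsumexp(per_state),
               tolerance = 1e-10)
})

test_that("near-diagonal chains with separated emissions decode the true path", {
  Q <- 3
  tpm <- matrix(0.05, Q, Q); diag(tpm) <- 0.9
  em <- lapply(1:Q, function(j)
    actihmm:::new_gaussian_mixture(1, matrix(c(j * 10, 0), 1), list(diag(2))))
  m <- chmm(omm(paste0("s", 1:Q), rep(1 / Q, Q), tpm), em)
  sim <- simulate_chmm(m, 200, seed = 0)
  # observations exactly at the state means
  X <- t(vapply(match(sim$states, m$omm$labels),
                function(j) m$emissions[[j]]$means[1, ], numeric(2)))
  expect_identical(viterbi_decode(m, X)$path, sim$states)
})

test_that("first-phase training reuses event counting and closed-form fits", {
  lib <- tiny_library(frames_per_class = 8, seed = 2)
  om <- tiny_omm()
  exps <- lapply(1:2, function(i) make_virtual_experiment(om, lib, 60, seed = i))
  m <- first_phase_train(exps, labels = om$labels)
  est <- estimate_omm(lapply(exps, function(e) e$label), labels = om$labels)
  expect_equal(m$omm$tpm, est$tpm)
  expect_equal(m$omm$prior, est$prior)
  # M = 1 state means are the exact sample means of that state's frames
  all_frames <- dplyr::bind_rows(exps)
  for (s in om$labels) {
    Xs <- feature_matrix(all_frames[all_frames$label == s, ])
    expect_equal(unname(m$emissions[[s]]$means[1, ]), unname(colMeans(Xs)))
  }
  expect_error(first_phase_train(exps, labels = c(om$labels, "absent")), "absent")
})

test_that("supervised training recovers a known low-dimensional model", {
  tpm <- rbind(c(0.8, 0.15, 0.05), c(0.1, 0.8, 0.1), c(0.05, 0.15, 0.8))
  em <- lapply(1:3, function(j)
    actihmm:::new_gaussian_mixture(1, matrix(c(3 * j, -3 * j), 1),
                                   list(0.25 * diag(2))))
  truth <- chmm(omm(paste0("s", 1:3), rep(1 / 3, 3), tpm), em)
  sim <- simulate_chmm(truth, 5000, seed = 0)
  train <- dplyr::bind_cols(tibble::tibble(label = sim$states),
                            tibble::as_tibble(sim$observations, .name_repair = ~ c("x1", "x2")))
  fit <- first_phase_train(train, labels = truth$omm$labels)
  expect_lt(max(abs(fit$omm$tpm - tpm)), 0.03)
  for (j in 1:3) {
    expect_lt(max(abs(fit$emissions[[j]]$means - truth$emissions[[j]]$means)), 0.1)
  }
})

test_that("Baum-Welch is monotone and stable at the generating parameters", {
  m <- random_chmm(Q = 3, d = 2, seed = 9)
  X <- simulate_chmm(m, 400, seed = 10)$observations
  ref <- baum_welch_refine(m, X, mode = "all", tol = 1e-4, max_iter = 15)
  tr <- attr(ref, "loglik_trace")
  expect_true(all(diff(tr) >= -1e-6))

  # starting at the generating parameters the first gain is tiny
  long <- simulate_chmm(m, 3000, seed = 11)$observations
  ref2 <- baum_welch_refine(m, long, mode = "transitions_only",
                            tol = 1e-4, max_iter = 2)
  tr2 <- attr(ref2, "loglik_trace")
  gain <- (tr2[2] - tr2[1]) / abs(tr2[1])
  expect_lt(gain, 10 * 1e-4)
})

test_that("transition-only refinement adapts to a changed transition regime", {
  em <- lapply(1:2, function(j)
    actihmm:::new_gaussian_mixture(1, matrix(c(5 * j, 0), 1), list(diag(2))))
  A1 <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  A2 <- rbind(c(0.55, 0.45), c(0.45, 0.55))
  m1 <- chmm(omm(c("u", "v"), c(0.5, 0.5), A1), em)
  m2 <- chmm(omm(c("u", "v"), c(0.5, 0.5), A2), em)
  X <- simulate_chmm(m2, 1500, seed = 0)$observations
  refined <- baum_welch_refine(m1, X, mode = "transitions_only", max_iter = 30)
  expect_lt(max(abs(refined$omm$tpm - A2)), max(abs(A1 - A2)))
  # emissions untouched in transitions_only mode
  expect_equal(refined$emissions[[1]]$means, em[[1]]$means)
})

test_that("full refinement improves transition recovery over the first phase", {
  improved <- 0L
  for (i in 1:5) {
    truth <- random_chmm(Q = 2, d = 2, seed = 300 + i, sep = 4)
    sim <- simulate_chmm(truth, 600, seed = 400 + i)
    train <- dplyr::bind_cols(tibble::tibble(label = sim$states),
                              tibble::as_tibble(sim$observations,
                                                .name_repair = ~ c("x1", "x2")))
    first <- first_phase_train(train, labels = truth$omm$labels)
    test_obs <- simulate_chmm(truth, 600, seed = 500 + i)$observations
    refined <- baum_welch_refine(first, test_obs, mode = "all", max_iter = 25)
    e_first <- max(abs(first$omm$tpm - truth$omm$tpm))
    e_ref <- max(abs(refined$omm$tpm - truth$omm$tpm))
    improved <- improved + (e_ref <= e_first + 1e-6)
  }
  expect_gte(improved, 3L)
})

test_that("log-space recursions survive very long sequences", {
  m <- random_chmm(Q = 2, d = 2, seed = 12)
  X <- simulate_chmm(m, 10000, seed = 13)$observations
  ll <- forward_loglik(m, X)
  expect_true(is.finite(ll))
  vd <- viterbi_decode(m, X)
  expect_true(is.finite(vd$log_prob))
  expect_length(vd$path, 10000L)
})

test_that("sequence classification matches Viterbi without a rejector", {
  m <- random_chmm(Q = 3, d = 2, seed = 14)
  X <- simulate_chmm(m, 50, seed = 15)$observations
  expect_identical(classify_sequence(m, X), viterbi_decode(m, X)$path)
})

test_that("rejected frames are skipped and labelled SPURIOUS", {
  m <- random_chmm(Q = 2, d = 2, seed = 16, sep = 5)
  sim <- simulate_chmm(m, 40, seed = 17)
  X <- sim$observations
  X[c(5, 20), ] <- 1e3        # impossible frames
  scores <- frame_score(m, X)
  rej <- calibrate_threshold(scores[-c(5, 20)], scores[c(5, 20)])
  out <- classify_sequence(m, X, rejector = rej)
  expect_length(out, 40L)
  expect_identical(which(out == "SPURIOUS"), c(5L, 20L))

  all_bad <- matrix(1e3, 4, 2)
  expect_error(classify_sequence(m, all_bad, rejector = rej), "no classifiable")
})
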