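# Shared fixtures and independent oracles used across test files.

# deterministic multi-channel recording: sinusoids + noise
toy_recording <- function(n = 1024, channels = 2, rate = 76.25, seed = 1) {
  withr::with_seed(seed, {
    tt <- (seq_len(n) - 1) / rate
    x <- sapply(seq_len(channels), function(c_)
      c_ + sin(2 * pi * (1 + c_ / 2) * tt) + rnorm(n, 0, 0.1))
    raw_recording(x, rate = rate)
  })
}

# two well-separated Gaussian classes in d dimensions
toy_classes <- function(n_per = 30, d = 3, gap = 6, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * d), n_per, d),
               matrix(rnorm(n_per * d, mean = gap), n_per, d))
    colnames(x) <- paste0("f", seq_len(d))
    dplyr::bind_cols(
      tibble::tibble(label = rep(c("a", "b"), each = n_per)),
      tibble::as_tibble(x)
    )
  })
}

# random small cHMM with unit-ish covariances and separated means
random_chmm <- function(Q = 3, d = 2, seed = 1, sep = 3) {
  withr::with_seed(seed, {
    tpm <- matrix(rgamma(Q * Q, 1), Q)
    tpm <- tpm / rowSums(tpm)
    prior <- rgamma(Q, 1); prior <- prior / sum(prior)
    em <- lapply(seq_len(Q), function(j) {
      A <- matrix(rnorm(d * d, sd = 0.2), d)
      actihmm:::new_gaussian_mixture(
        1, matrix(rnorm(d, mean = j * sep), 1), list(diag(d) + A %*% t(A)))
    })
    chmm(omm(paste0("s", seq_len(Q)), prior, tpm), em)
  })
}

# exhaustive-path oracles for the forward likelihood and Viterbi decoding
brute_force_paths <- function(model, X) {
  Q <- n_states(model)
  Tn <- nrow(X)
  ll <- actihmm:::emission_logdens(model, X)
  paths <- as.matrix(expand.grid(rep(list(seq_len(Q)), Tn)))
  lp <- apply(paths, 1, function(p) {
    v <- log(model$omm$prior[p[1]]) + ll[1, p[1]]
    if (Tn > 1) for (t in 2:Tn) v <- v + log(model$omm$tpm[p[t - 1], p[t]]) + ll[t, p[t]]
    v
  })
  list(loglik = actihmm:::logsumexp(lp),
       best_logprob = max(lp),
       best_path = model$omm$labels[paths[which.max(lp), ]])
}

# tiny labelled feature library over a reduced activity vocabulary
tiny_library <- function(frames_per_class = 6, seed = 1) {
  specs <- default_activity_specs()[c("lying", "walking", "cycling")]
  build_frame_library(specs, frames_per_class = frames_per_class, seed = seed)
}

# a matching 3-state OMM for the tiny library
tiny_omm <- function() {
  omm(c("lying", "walking", "cycling"),
      prior = c(0.4, 0.4, 0.2),
      tpm = rbind(c(0.90, 0.08, 0.02),
                  c(0.05, 0.85, 0.10),
                  c(0.05, 0.15, 0.80)))
}
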