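# Continuous-emission hidden Markov model with Gaussian-mixture emissions:
# two-phase supervised training, forward likelihood, Viterbi decoding,
# Baum-Welch refinement and sequence classification.

#' Construct a Gaussian-emission hidden Markov model
#'
#' A cHMM couples an observable Markov model over activity states with one
#' Gaussian-mixture emission density per state: each state `j` emits feature
#' vectors from \eqn{b_j(x) = \sum_m c_{jm} N(x; \mu_{jm}, \Sigma_{jm})}
#' with mixture weights summing to 1.
#'
#' @param omm An [omm()] holding the prior and transition matrix.
#' @param emissions A list of `gaussian_mixture` objects, one per state, in
#'   the OMM's label order. Each has fields `weights`, `means`
#'   (`M x d`) and `covariances` (list of `M` `d x d` matrices).
#' @return A `chmm` object.
#' @export
chmm <- function(omm, emissions) {
  model <- structure(list(omm = omm, emissions = emissions), class = "chmm")
  validate_chmm(model)
}

#' @rdname chmm
#' @param model A `chmm`.
#' @export
validate_chmm <- function(model) {
  model$omm <- validate_omm(model$omm)
  Q <- length(model$omm$labels)
  if (length(model$emissions) != Q) {
    stop("number of emission models must equal the number of states", call. = FALSE)
  }
  d <- ncol(model$emissions[[1]]$means)
  for (j in seq_len(Q)) {
    e <- model$emissions[[j]]
    if (abs(sum(e$weights) - 1) > 1e-9) {
      stop(sprintf("mixture weights of state '%s' must sum to 1",
                   model$omm$labels[j]), call. = FALSE)
    }
    if (ncol(e$means) != d) stop("inconsistent emission dimensions", call. = FALSE)
  }
  names(model$emissions) <- model$omm$labels
  model
}

#' @rdname chmm
#' @export
n_states <- function(model) length(model$omm$labels)

.obs_matrix <- function(model, obs) {
  X <- if (is.matrix(obs)) obs else feature_matrix(obs)
  d <- ncol(model$emissions[[1]]$means)
  if (!is.null(colnames(X))) {
    fn <- colnames(model$emissions[[1]]$means)
    if (!is.null(fn) && all(fn %in% colnames(X))) X <- X[, fn, drop = FALSE]
  }
  if (ncol(X) != d) {
    stop(sprintf("observation dimension %d does not match emission dimension %d",
                 ncol(X), d), call. = FALSE)
  }
  if (nrow(X) < 1L) stop("empty observation sequence", call. = FALSE)
  X
}

# T x Q matrix of log emission densities
emission_logdens <- function(model, X) {
  vapply(model$emissions, function(e) gm_log_density(e, X), numeric(nrow(X))) |> rbind()
}

#' First-phase (supervised) training of a cHMM
#'
#' Trains the transition parameters separately from the emission
#' parameters, exploiting the annotations: the prior and transition matrix
#' are estimated by event counting over the label sequences
#' ([estimate_omm()]), and each state's Gaussian-mixture emission is fitted
#' from the frames labelled with that state only — the same computation as
#' the class-conditional densities of the single-frame GMM classifier.
#'
#' @param experiments A list of labelled experiments; each element is a data
#'   frame with a `label` column and feature columns (e.g. a
#'   [make_virtual_experiment()] output). A single data frame is accepted.
#' @param M Mixture components per state (default 1: closed-form fit).
#' @param smoothing Additive smoothing for the event counts.
#' @param emission_frames Optional separate labelled feature table used to
#'   fit the emissions (e.g. a K-frames-per-class training library); the
#'   transition counts still come from `experiments`.
#' @param labels Optional state ordering; defaults to sorted unique labels.
#' @param seed Seed for mixture initialisation when `M > 1`.
#' @return A `chmm`.
#' @export
first_phase_train <- function(experiments, M = 1, smoothing = 0,
                              emission_frames = NULL, labels = NULL, seed = 1) {
  if (is.data.frame(experiments)) experiments <- list(experiments)
  seqs <- lapply(experiments, function(e) as.character(e$label))
  emis_data <- emission_frames %||% dplyr::bind_rows(
    lapply(experiments, function(e) e[setdiff(names(e), c("spurious", "frame_start"))]))
  labels <- labels %||% sort(unique(unlist(seqs)))
  present <- unique(as.character(emis_data$label))
  missing <- setdiff(labels, present)
  if (length(missing) > 0L) {
    stop(sprintf("no training frames for state(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  om <- estimate_omm(seqs, labels = labels, smoothing = smoothing)
  X <- feature_matrix(emis_data)
  lab <- as.character(emis_data$label)
  emissions <- fit_class_gaussians(X, lab, labels, M = M, seed = seed)
  chmm(om, unname(emissions))
}

#' Forward log-likelihood of an observation sequence
#'
#' Evaluates \eqn{\log P(\mathrm{obs} \mid \lambda)} with the forward
#' recursion computed in log space (log-sum-exp), so sequences of tens of
#' thousands of frames neither overflow nor underflow.
#'
#' @param model A `chmm`.
#' @param obs A numeric matrix or feature table (rows = frames).
#' @return A single log-likelihood value.
#' @export
forward_loglik <- function(model, obs) {
  model <- validate_chmm(model)
  X <- .obs_matrix(model, obs)
  ll <- emission_logdens(model, X)
  lA <- log(model$omm$tpm)
  la <- log(model$omm$prior) + ll[1, ]
  Tn <- nrow(X)
  if (Tn > 1L) {
    for (t in 2:Tn) {
      la <- vapply(seq_along(la), function(j) logsumexp(la + lA[, j]), numeric(1)) +
        ll[t, ]
    }
  }
  logsumexp(la)
}

#' Viterbi decoding of the most likely state path
#'
#' Dynamic-programming maximisation of the joint path probability in log
#' space. Ties at each backtracking step are broken towards the lower state
#' index.
#'
#' @inheritParams forward_loglik
#' @return A list with `path` (character state labels) and `log_prob` (log
#'   probability of the decoded path).
#' @export
viterbi_decode <- function(model, obs) {
  model <- validate_chmm(model)
  X <- .obs_matrix(model, obs)
  ll <- emission_logdens(model, X)
  lA <- log(model$omm$tpm)
  Q <- n_states(model)
  Tn <- nrow(X)
  delta <- matrix(-Inf, Tn, Q)
  psi <- matrix(1L, Tn, Q)
  delta[1, ] <- log(model$omm$prior) + ll[1, ]
  if (Tn > 1L) {
    for (t in 2:Tn) {
      for (j in seq_len(Q)) {
        cand <- delta[t - 1, ] + lA[, j]
        psi[t, j] <- which.max(cand)
        delta[t, j] <- cand[psi[t, j]] + ll[t, j]
      }
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  if (Tn > 1L) for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  list(path = model$omm$labels[path], log_prob = max(delta[Tn, ]))
}

# scaled forward-backward pass; returns log-gamma, per-step xi sums and loglik
.forward_backward <- function(model, X) {
  ll <- emission_logdens(model, X)
  lA <- log(model$omm$tpm)
  Q <- ncol(ll); Tn <- nrow(ll)
  lalpha <- matrix(-Inf, Tn, Q)
  lbeta <- matrix(0, Tn, Q)
  lalpha[1, ] <- log(model$omm$prior) + ll[1, ]
  if (Tn > 1L) {
    for (t in 2:Tn) {
      for (j in seq_len(Q)) lalpha[t, j] <- logsumexp(lalpha[t - 1, ] + lA[, j]) + ll[t, j]
    }
    for (t in (Tn - 1):1) {
      for (i in seq_len(Q)) lbeta[t, i] <- logsumexp(lA[i, ] + ll[t + 1, ] + lbeta[t + 1, ])
    }
  }
  loglik <- logsumexp(lalpha[Tn, ])
  lgamma_ <- lalpha + lbeta - loglik
  xi_sum <- matrix(0, Q, Q)
  if (Tn > 1L) {
    for (t in seq_len(Tn - 1L)) {
      lxi <- outer(lalpha[t, ], ll[t + 1, ] + lbeta[t + 1, ], `+`) + lA - loglik
      xi_sum <- xi_sum + exp(lxi)
    }
  }
  list(lgamma = lgamma_, xi_sum = xi_sum, loglik = loglik, logdens = ll)
}

#' Baum-Welch refinement (second-phase training)
#'
#' Refines a supervised first-phase model by expectation-maximisation on an
#' unlabelled observation sequence. The default mode re-estimates only the
#' prior and transition matrix while holding the emissions fixed — the
#' second phase exists chiefly to adapt the model to transition behaviour
#' not represented in the training sentences; `mode = "all"` additionally
#' updates the mixture weights, means and covariances (with the usual
#' covariance floor).
#'
#' Iterations stop when the relative log-likelihood gain drops below `tol`
#' or after `max_iter` iterations; the log-likelihood sequence is monotone
#' non-decreasing and is returned in the `loglik_trace` attribute.
#'
#' @inheritParams forward_loglik
#' @param mode `"transitions_only"` (default) or `"all"`.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return The refined `chmm`, with attribute `loglik_trace`.
#' @export
baum_welch_refine <- function(model, obs, mode = c("transitions_only", "all"),
                              tol = 1e-4, max_iter = 100) {
  mode <- match.arg(mode)
  model <- validate_chmm(model)
  X <- .obs_matrix(model, obs)
  if (nrow(X) < 2L) stop("need at least 2 observations for refinement", call. = FALSE)
  Q <- n_states(model)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    fb <- .forward_backward(model, X)
    trace <- c(trace, fb$loglik)
    gamma_ <- exp(fb$lgamma)
    prior <- gamma_[1, ] / sum(gamma_[1, ])
    denom <- colSums(gamma_[-nrow(gamma_), , drop = FALSE])
    tpm <- model$omm$tpm
    for (i in seq_len(Q)) {
      if (denom[i] > 1e-12) tpm[i, ] <- fb$xi_sum[i, ] / denom[i]
    }
    tpm <- pmax(tpm, 0)
    tpm <- tpm / rowSums(tpm)
    model$omm$prior <- pmax(prior, 0) / sum(pmax(prior, 0))
    model$omm$tpm <- tpm
    if (mode == "all") {
      model$emissions <- lapply(seq_len(Q), function(j) {
        e <- model$emissions[[j]]
        M <- length(e$weights)
        comp <- gm_component_log(e, X)                     # T x M
        comp <- comp - apply(comp, 1L, logsumexp)
        r <- exp(comp) * gamma_[, j]                       # state-and-component resp.
        nk <- pmax(colSums(r), 1e-10)
        means <- t(r) %*% X / nk
        covs <- lapply(seq_len(M), function(m) {
          centred <- sweep(X, 2L, means[m, ])
          S <- t(centred * r[, m]) %*% centred / nk[m]
          regularize_cov(S, nk[m])
        })
        colnames(means) <- colnames(e$means)
        new_gaussian_mixture(nk / sum(nk), means, covs)
      })
      names(model$emissions) <- model$omm$labels
    }
    if (it > 1L) {
      gain <- trace[it] - trace[it - 1L]
      if (gain < tol * abs(trace[it - 1L])) break
    }
  }
  final <- forward_loglik(model, X)
  attr(model, "loglik_trace") <- c(trace, final)
  model
}

#' Simulate an observation sequence from a cHMM
#'
#' Generates a state path from the embedded OMM and draws one feature
#' vector per step from the corresponding state's Gaussian mixture.
#'
#' @inheritParams forward_loglik
#' @param n_steps Number of frames to simulate.
#' @param seed Optional seed.
#' @return A list with `states` (character) and `observations` (matrix).
#' @export
simulate_chmm <- function(model, n_steps, seed = NULL) {
  model <- validate_chmm(model)
  with_seed_if(seed, {
    states <- generate_states(model$omm, n_steps)
    idx <- match(states, model$omm$labels)
    d <- ncol(model$emissions[[1]]$means)
    X <- matrix(NA_real_, n_steps, d)
    for (t in seq_len(n_steps)) {
      e <- model$emissions[[idx[t]]]
      m <- sample.int(length(e$weights), 1L, prob = e$weights)
      X[t, ] <- rmvnorm_chol(1, e$means[m, ], e$covariances[[m]])
    }
    colnames(X) <- colnames(model$emissions[[1]]$means)
    list(states = states, observations = X)
  })
}

#' Classify a frame sequence with the sequential cHMM classifier
#'
#' Optionally screens every frame with a likelihood-threshold rejector
#' ([calibrate_threshold()]): frames whose emission score falls below the
#' threshold are flagged `"SPURIOUS"` and removed before decoding, so the
#' Markov chain skips them; the surviving frames receive the labels of the
#' Viterbi path.
#'
#' @inheritParams forward_loglik
#' @param rejector Optional `rejection_model`.
#' @param refine Optional on-the-fly second-phase mode applied to the kept
#'   frames before decoding: `"none"` (default), `"transitions_only"` or
#'   `"all"`.
#' @param refine_max_iter Iteration cap for on-the-fly refinement.
#' @return Character vector of per-frame labels, same length as the input;
#'   rejected frames are labelled `"SPURIOUS"`.
#' @export
classify_sequence <- function(model, obs, rejector = NULL,
                              refine = c("none", "transitions_only", "all"),
                              refine_max_iter = 20) {
  refine <- match.arg(refine)
  model <- validate_chmm(model)
  X <- .obs_matrix(model, obs)
  keep <- rep(TRUE, nrow(X))
  if (!is.null(rejector)) {
    keep <- !reject_spurious(rejector, model$emissions, X)
    if (!any(keep)) stop("no classifiable frames: all frames rejected", call. = FALSE)
  }
  Xk <- X[keep, , drop = FALSE]
  if (refine != "none" && nrow(Xk) >= 2L) {
    model <- baum_welch_refine(model, Xk, mode = refine, max_iter = refine_max_iter)
  }
  out <- rep("SPURIOUS", nrow(X))
  out[keep] <- viterbi_decode(model, Xk)$path
  out
}

#' @export
print.chmm <- function(x, ...) {
  cat(sprintf("<chmm> %d states, d = %d, M = %d\n", n_states(x),
              ncol(x$emissions[[1]]$means), length(x$emissions[[1]]$weights)))
  invisible(x)
}
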