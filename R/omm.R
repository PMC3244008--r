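# Observable Markov model of composite activities: a prior probability
# vector over activity primitives plus a transition probability matrix.

#' Construct an observable Markov model (OMM)
#'
#' An OMM describes how activity primitives ("motor words") chain into a
#' composite activity ("motor sentence") as a first-order Markov chain:
#' `prior[i]` is the probability that the sentence starts in state `i`, and
#' `tpm[i, j]` the probability of moving from state `i` to state `j`.
#'
#' @param labels Character vector of state (activity) names.
#' @param prior Length-`Q` probability vector; non-negative, sums to 1.
#' @param tpm `Q x Q` transition probability matrix; non-negative entries,
#'   each row summing to 1 (within 1e-9).
#' @return An `omm` object.
#' @export
omm <- function(labels, prior, tpm) {
  labels <- as.character(labels)
  tpm <- as.matrix(tpm)
  model <- structure(list(labels = labels, prior = as.numeric(prior), tpm = tpm),
                     class = "omm")
  validate_omm(model)
}

#' @rdname omm
#' @param model An `omm`.
#' @export
validate_omm <- function(model) {
  Q <- length(model$labels)
  if (Q < 1L) stop("an OMM needs at least one state", call. = FALSE)
  if (length(model$prior) != Q) stop("`prior` length must equal the number of states",
                                     call. = FALSE)
  if (any(model$prior < -1e-12)) stop("`prior` must be non-negative", call. = FALSE)
  if (abs(sum(model$prior) - 1) > 1e-9) stop("`prior` must sum to 1", call. = FALSE)
  if (!all(dim(model$tpm) == c(Q, Q))) stop("`tpm` must be Q x Q", call. = FALSE)
  if (any(model$tpm < -1e-12)) stop("transition probabilities must be non-negative",
                                    call. = FALSE)
  rs <- rowSums(model$tpm)
  bad <- which(abs(rs - 1) > 1e-9)
  if (length(bad) > 0L) {
    stop(sprintf("transition matrix rows must sum to 1; violated by row '%s' (sum %.6f)",
                 model$labels[bad[1]], rs[bad[1]]), call. = FALSE)
  }
  dimnames(model$tpm) <- list(model$labels, model$labels)
  names(model$prior) <- model$labels
  model
}

#' Estimate an OMM from labelled state sequences by event counting
#'
#' Transition probabilities are relative frequencies of observed
#' transitions, optionally Laplace-smoothed:
#' `a_ij = (n_ij + delta) / (n_i + Q * delta)`, where `n_ij` counts `i -> j`
#' transitions and `n_i` departures from `i`. The prior is estimated from
#' sequence starts the same way. With `delta = 0`, a state that is never
#' departed from receives a uniform row (with a warning).
#'
#' @param sequences A list of character vectors (state sequences), or a
#'   single character vector.
#' @param labels State set and ordering; defaults to the sorted unique
#'   labels observed.
#' @param smoothing Additive smoothing constant `delta >= 0` (default 0,
#'   pure event counting).
#' @return An `omm`.
#' @export
estimate_omm <- function(sequences, labels = NULL, smoothing = 0) {
  if (!is.list(sequences)) sequences <- list(sequences)
  sequences <- lapply(sequences, as.character)
  if (length(sequences) < 1L) stop("need at least one sequence", call. = FALSE)
  .assert_scalar_number(smoothing, "smoothing")
  if (smoothing < 0) stop("`smoothing` must be >= 0", call. = FALSE)
  seen <- unique(unlist(sequences))
  labels <- labels %||% sort(seen)
  unknown <- setdiff(seen, labels)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown label(s) in sequences: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  Q <- length(labels)
  trans <- matrix(0, Q, Q, dimnames = list(labels, labels))
  starts <- stats::setNames(numeric(Q), labels)
  for (s in sequences) {
    starts[s[1]] <- starts[s[1]] + 1
    if (length(s) > 1L) {
      from <- s[-length(s)]; to <- s[-1]
      for (t in seq_along(from)) trans[from[t], to[t]] <- trans[from[t], to[t]] + 1
    }
  }
  departures <- rowSums(trans)
  tpm <- (trans + smoothing) / (departures + Q * smoothing)
  empty <- departures == 0 & smoothing == 0
  if (any(empty)) {
    warning(sprintf("state(s) never departed from, using uniform row: %s",
                    paste(labels[empty], collapse = ", ")), call. = FALSE)
    tpm[empty, ] <- 1 / Q
  }
  prior <- (starts + smoothing) / (length(sequences) + Q * smoothing)
  omm(labels, prior, tpm)
}

#' Generate a state sequence from an OMM
#'
#' Draws the initial state from the prior and each subsequent state from
#' the transition row of the current state.
#'
#' @param model An `omm`.
#' @param n_steps Sequence length (>= 1).
#' @param seed Optional integer seed for reproducibility; `NULL` uses the
#'   current RNG state.
#' @return Character vector of state labels of length `n_steps`.
#' @export
generate_states <- function(model, n_steps, seed = NULL) {
  model <- validate_omm(model)
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("`n_steps` must be >= 1", call. = FALSE)
  with_seed_if(seed, {
    Q <- length(model$labels)
    idx <- integer(n_steps)
    idx[1] <- sample.int(Q, 1L, prob = model$prior)
    for (t in seq_len(n_steps - 1L)) {
      idx[t + 1L] <- sample.int(Q, 1L, prob = model$tpm[idx[t], ])
    }
    model$labels[idx]
  })
}

#' Stationary distribution of an OMM
#'
#' The left eigenvector of the transition matrix with eigenvalue 1,
#' normalised to sum to 1.
#'
#' @param model An `omm`.
#' @return Named probability vector.
#' @export
stationary_distribution <- function(model) {
  model <- validate_omm(model)
  e <- eigen(t(model$tpm))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- pmax(v / sum(v), 0)
  stats::setNames(v / sum(v), model$labels)
}

#' Reference transition matrix for the seven-activity vocabulary
#'
#' A seven-state OMM over the activity vocabulary lying, cycling, climbing
#' (stairs), walking, running, sitting, standing, with strong
#' self-transitions for sustained activities (e.g. lying persists with
#' probability 0.95). Shipped as the package's default scenario for
#' simulating composite activities; the prior is the chain's stationary
#' distribution.
#'
#' @return An `omm` with `Q = 7` states.
#' @export
seven_activity_omm <- function() {
  labels <- c("lying", "cycling", "climbing", "walking", "running", "sitting", "standing")
  tpm <- matrix(c(
    0.9500, 0.0000, 0.0000, 0.0000, 0.0000, 0.0100, 0.0400,
    0.0001, 0.8999, 0.0000, 0.0400, 0.0000, 0.0100, 0.0500,
    0.0001, 0.0000, 0.6199, 0.2500, 0.0100, 0.0200, 0.1000,
    0.0001, 0.0100, 0.0300, 0.7999, 0.0200, 0.0700, 0.0700,
    0.0001, 0.0100, 0.0100, 0.3500, 0.3999, 0.0100, 0.2200,
    0.0200, 0.0000, 0.0100, 0.0400, 0.0000, 0.8500, 0.0900,
    0.0100, 0.0300, 0.0100, 0.1800, 0.0300, 0.1200, 0.6200
  ), nrow = 7, byrow = TRUE, dimnames = list(labels, labels))
  tpm <- tpm / rowSums(tpm)   # row-normalise (guards against rounded entries)
  prior <- stationary_distribution(
    structure(list(labels = labels, prior = rep(1 / 7, 7), tpm = tpm), class = "omm"))
  omm(labels, prior, tpm)
}

#' @export
print.omm <- function(x, ...) {
  cat(sprintf("<omm> %d states: %s\n", length(x$labels),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}
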