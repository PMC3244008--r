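# Likelihood-threshold rejection of out-of-vocabulary ("garbage") frames,
# with ROC-based threshold calibration.

.emissions_of <- function(x) {
  if (inherits(x, "chmm")) x$emissions else x
}

#' Emission score of a feature frame
#'
#' The likelihood of a frame given the Gaussian-mixture structure that
#' models the cHMM emissions, summarised as the maximum over states of the
#' log emission density \eqn{\max_j \log b_j(x)}. The maximum is used
#' because it does not depend on any prior over states; frames from
#' activities outside the trained vocabulary score far below frames the
#' model has seen.
#'
#' @param emissions A `chmm` or its list of per-state `gaussian_mixture`
#'   emissions.
#' @param x A single feature vector, matrix of frames, or feature table.
#' @return Numeric score(s), one per frame.
#' @export
frame_score <- function(emissions, x) {
  em <- .emissions_of(emissions)
  X <- if (is.matrix(x)) x else if (is.data.frame(x)) feature_matrix(x) else rbind(x)
  fn <- colnames(em[[1]]$means)
  if (!is.null(fn) && !is.null(colnames(X)) && all(fn %in% colnames(X))) {
    X <- X[, fn, drop = FALSE]
  }
  if (ncol(X) != ncol(em[[1]]$means)) {
    stop("feature dimension does not match emission models", call. = FALSE)
  }
  per_state <- vapply(em, function(e) gm_log_density(e, X), numeric(nrow(X))) |> rbind()
  apply(per_state, 1L, max)
}

#' Calibrate the spurious-frame rejection threshold by ROC analysis
#'
#' Sweeps every candidate threshold (midpoints between consecutive sorted
#' scores) over scores of genuine ("inlier") and garbage ("outlier")
#' frames. At a threshold `t`, sensitivity is the fraction of outliers
#' scoring below `t` (correctly rejected) and specificity the fraction of
#' inliers scoring at or above `t` (correctly kept). The returned
#' operating point maximises Youden's index (sensitivity + specificity),
#' ties resolved towards the lower threshold; the full ROC curve is kept.
#'
#' @param inlier_scores Scores of genuine frames ([frame_score()]).
#' @param outlier_scores Scores of garbage frames.
#' @return A `rejection_model` with fields `threshold`, `score_rule`,
#'   `sensitivity`, `specificity` and the ROC tibble `roc`.
#' @export
calibrate_threshold <- function(inlier_scores, outlier_scores) {
  stopifnot(length(inlier_scores) > 0L, length(outlier_scores) > 0L)
  all_scores <- sort(unique(c(inlier_scores, outlier_scores)))
  cand <- c(all_scores[1] - 1,
            if (length(all_scores) > 1L)
              (all_scores[-1] + all_scores[-length(all_scores)]) / 2,
            all_scores[length(all_scores)] + 1)
  sens <- vapply(cand, function(t) mean(outlier_scores < t), numeric(1))
  spec <- vapply(cand, function(t) mean(inlier_scores >= t), numeric(1))
  youden <- sens + spec
  best <- which(youden == max(youden))[1]   # candidates ascend: first = lowest
  structure(
    list(threshold = cand[best], score_rule = "max_state_log_density",
         sensitivity = sens[best], specificity = spec[best],
         roc = tibble::tibble(threshold = cand, sensitivity = sens,
                              specificity = spec)),
    class = "rejection_model"
  )
}

#' Flag spurious frames by likelihood threshold
#'
#' @param rejection A `rejection_model`.
#' @param emissions A `chmm` or emission list (see [frame_score()]).
#' @param obs Frames to screen.
#' @return Logical mask, `TRUE` for frames whose score falls below the
#'   threshold (to be rejected).
#' @export
reject_spurious <- function(rejection, emissions, obs) {
  stopifnot(inherits(rejection, "rejection_model"))
  frame_score(emissions, obs) < rejection$threshold
}

#' Area under the rejection ROC curve
#'
#' @param rejection A `rejection_model`.
#' @return AUC in `[0, 1]`, by trapezoidal integration of sensitivity
#'   against false-positive rate (1 - specificity).
#' @export
rejection_auc <- function(rejection) {
  stopifnot(inherits(rejection, "rejection_model"))
  fpr <- 1 - rejection$roc$specificity
  ord <- order(fpr, rejection$roc$sensitivity)
  min(max(trapz(fpr[ord], rejection$roc$sensitivity[ord]), 0), 1)
}

#' @export
print.rejection_model <- function(x, ...) {
  cat(sprintf("<rejection_model> threshold %.4g (%s); sensitivity %.3f, specificity %.3f\n",
              x$threshold, x$score_rule, x$sensitivity, x$specificity))
  invisible(x)
}
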