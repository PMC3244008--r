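# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# trapezoidal rule on an (ordered) grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Columns of a feature table that carry metadata rather than features.
.meta_cols <- c("label", "spurious", "frame_start")

#' Extract the numeric feature matrix from a feature table
#'
#' Feature tables produced by [extract_features()] and
#' [build_frame_library()] mix metadata columns (`label`, `spurious`,
#' `frame_start`) with feature columns. This helper drops the metadata and
#' returns the features as a numeric matrix, which is the representation the
#' classifiers and the hidden Markov machinery work on.
#'
#' @param data A data frame with feature columns and optional metadata
#'   columns.
#' @return A numeric matrix, one row per frame.
#' @export
feature_matrix <- function(data) {
  stopifnot(is.data.frame(data))
  keep <- setdiff(names(data), .meta_cols)
  m <- as.matrix(data[keep])
  storage.mode(m) <- "double"
  m
}

.assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
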