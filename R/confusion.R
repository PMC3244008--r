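# Confusion matrices and aggregate accuracy.

#' Build a confusion matrix
#'
#' @param truth True activity labels.
#' @param estimate Predicted labels, same length.
#' @param labels Optional label set fixing row/column order; defaults to
#'   the sorted union of `truth` and `estimate`.
#' @return A `confusion_matrix`: an integer matrix (true class in rows,
#'   predicted in columns) with an `accuracy()` accessor.
#' @export
confusion_matrix <- function(truth, estimate, labels = NULL) {
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  stopifnot(length(truth) == length(estimate))
  labels <- labels %||% sort(unique(c(truth, estimate)))
  counts <- table(factor(truth, levels = labels), factor(estimate, levels = labels))
  m <- matrix(as.integer(counts), nrow = length(labels),
              dimnames = list(truth = labels, estimate = labels))
  structure(list(counts = m, labels = labels), class = "confusion_matrix")
}

#' @rdname confusion_matrix
#' @param cm A `confusion_matrix`.
#' @return `accuracy()`: the fraction of outcomes on the diagonal.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm$counts)
  if (total == 0) return(NA_real_)
  sum(diag(cm$counts)) / total
}

#' Evaluate a single-frame classifier on a labelled test set
#'
#' @param model A `frame_classifier`.
#' @param test A data frame with a `label` column and feature columns.
#' @param ... Passed to [predict.frame_classifier()].
#' @return A `confusion_matrix` over the union of test and model labels.
#' @export
evaluate_classifier <- function(model, test, ...) {
  pred <- predict(model, test, ...)
  confusion_matrix(test$label, pred,
                   labels = sort(unique(c(model$classes, as.character(test$label)))))
}

#' Aggregate confusion matrices across subjects or runs
#'
#' Elementwise sum of matrices sharing the same label set, as used to pool
#' classification outcomes over all tested subjects before computing the
#' aggregate accuracy.
#'
#' @param cms A list of `confusion_matrix` objects.
#' @return A single `confusion_matrix`.
#' @export
aggregate_confusions <- function(cms) {
  stopifnot(length(cms) >= 1L, all(vapply(cms, inherits, logical(1), "confusion_matrix")))
  labs <- cms[[1]]$labels
  for (cm in cms[-1]) {
    if (!identical(cm$labels, labs)) stop("label sets differ across confusion matrices",
                                          call. = FALSE)
  }
  total <- Reduce(`+`, lapply(cms, `[[`, "counts"))
  structure(list(counts = total, labels = labs), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d classes, %d outcomes, accuracy %.4f\n",
              length(x$labels), sum(x$counts), accuracy(x)))
  print(x$counts)
  invisible(x)
}
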