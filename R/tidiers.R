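# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an observable Markov model into a long transition table
#'
#' @param x An `omm`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `probability`.
#' @export
tidy.omm <- function(x, ...) {
  x <- validate_omm(x)
  tidyr::expand_grid(from = x$labels, to = x$labels) |>
    dplyr::mutate(probability = as.vector(t(x$tpm)))
}

#' @rdname tidy.omm
#' @export
glance.omm <- function(x, ...) {
  tibble::tibble(n_states = length(x$labels),
                 min_self_transition = min(diag(x$tpm)),
                 max_self_transition = max(diag(x$tpm)))
}

#' Tidy a cHMM into a per-state emission summary
#'
#' @param x A `chmm`.
#' @param ... Unused.
#' @return A tibble with one row per state and mixture component: weight
#'   and the mean vector's Euclidean norm (a compact location summary).
#' @export
tidy.chmm <- function(x, ...) {
  purrr::imap(x$emissions, function(e, nm) {
    tibble::tibble(state = nm, component = seq_along(e$weights),
                   weight = e$weights,
                   mean_norm = sqrt(rowSums(e$means^2)))
  }) |> dplyr::bind_rows()
}

#' @rdname tidy.chmm
#' @export
glance.chmm <- function(x, ...) {
  tibble::tibble(n_states = n_states(x),
                 dimension = ncol(x$emissions[[1]]$means),
                 mixture_components = length(x$emissions[[1]]$weights))
}

#' Tidy a confusion matrix into long counts
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return A tibble with `truth`, `estimate`, `n`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tidyr::expand_grid(truth = x$labels, estimate = x$labels) |>
    dplyr::mutate(n = as.vector(t(x$counts)))
}

#' @rdname tidy.confusion_matrix
#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble::tibble(accuracy = accuracy(x), n = sum(x$counts),
                 n_classes = length(x$labels))
}

#' @rdname tidy.confusion_matrix
#' @param object A `confusion_matrix`.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy.confusion_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white", size = 3) +
    ggplot2::scale_y_discrete(limits = rev(object$labels)) +
    ggplot2::labs(x = "predicted", y = "true",
                  title = sprintf("accuracy %.3f", accuracy(object))) +
    ggplot2::theme_minimal()
}

#' Tidy a feature-selection result into a criterion curve
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return A tibble with `size`, `criterion` and `chosen`.
#' @export
tidy.selection_result <- function(x, ...) {
  tibble::tibble(size = seq_along(x$criterion_by_size),
                 criterion = x$criterion_by_size,
                 chosen = seq_along(x$criterion_by_size) == x$chosen_size)
}

#' @rdname tidy.selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(method = x$method, chosen_size = x$chosen_size,
                 best_criterion = x$criterion_by_size[x$chosen_size])
}

#' @rdname tidy.selection_result
#' @param object A `selection_result`.
#' @export
autoplot.selection_result <- function(object, ...) {
  df <- tidy.selection_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen)) +
    ggplot2::labs(x = "subset size", y = "k-NN separability criterion",
                  colour = "chosen") +
    ggplot2::theme_minimal()
}

#' Tidy a rejection model into its ROC curve
#'
#' @param x A `rejection_model`.
#' @param ... Unused.
#' @return The ROC tibble (`threshold`, `sensitivity`, `specificity`).
#' @export
tidy.rejection_model <- function(x, ...) x$roc

#' @rdname tidy.rejection_model
#' @export
glance.rejection_model <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, sensitivity = x$sensitivity,
                 specificity = x$specificity, auc = rejection_auc(x))
}

#' @rdname tidy.rejection_model
#' @param object A `rejection_model`.
#' @export
autoplot.rejection_model <- function(object, ...) {
  df <- object$roc
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = df[which.min(abs(df$threshold - object$threshold)), ],
                        colour = "red") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC %.3f", rejection_auc(object))) +
    ggplot2::theme_minimal()
}
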