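# Sequential feature selection under a k-NN class-separability criterion.

#' k-nearest-neighbour class-separability criterion
#'
#' Measures how well the labelled instances separate in feature space as the
#' ratio of inter-class to intra-class nearest-neighbour distances: the mean
#' (over instances) Euclidean distance to the `k` nearest neighbours of a
#' *different* class, divided by the mean distance to the `k` nearest
#' neighbours of the *same* class (excluding the instance itself). Values
#' near 1 indicate no separation; well-separated classes score far above 1.
#'
#' Features are standardised to zero mean and unit variance inside the
#' criterion so that no feature dominates through its scale; constant
#' features are neutral (they contribute nothing to any distance).
#'
#' @param data A data frame with a `label` column and numeric feature
#'   columns (metadata columns `frame_start`/`spurious` are ignored).
#' @param k Number of neighbours (default 1). Every class must have at
#'   least `k + 1` instances.
#' @return A single positive number.
#' @export
knn_separability <- function(data, k = 1) {
  prep <- .selection_prep(data, k)
  .knn_criterion(prep$x, prep$label_int, k)
}

.selection_prep <- function(data, k) {
  stopifnot(is.data.frame(data))
  if (!"label" %in% names(data)) stop("`data` must have a `label` column", call. = FALSE)
  labels <- as.character(data$label)
  x <- feature_matrix(data)
  if (length(unique(labels)) < 2L) stop("need at least 2 classes", call. = FALSE)
  cnt <- table(labels)
  if (any(cnt <= k)) {
    stop(sprintf("every class needs more than k = %d instances (violated by: %s)",
                 k, paste(names(cnt)[cnt <= k], collapse = ", ")), call. = FALSE)
  }
  list(x = x, label_int = as.integer(factor(labels)))
}

# criterion on a raw matrix; columns standardised here
.knn_criterion <- function(x, label_int, k) {
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0 | !is.finite(attr(x, "scaled:scale"))] <- 0
  x[is.nan(x)] <- 0
  dmat <- as.matrix(stats::dist(x))
  n <- nrow(dmat)
  intra <- inter <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(label_int == label_int[i])
    same <- setdiff(same, i)
    diff <- which(label_int != label_int[i])
    intra[i] <- mean(sort(dmat[i, same], partial = min(k, length(same)))[seq_len(k)])
    inter[i] <- mean(sort(dmat[i, diff], partial = min(k, length(diff)))[seq_len(k)])
  }
  denom <- mean(intra)
  if (denom < 1e-12) denom <- 1e-12
  mean(inter) / denom
}

.subset_criterion <- function(x, label_int, subset, k) {
  .knn_criterion(x[, subset, drop = FALSE], label_int, k)
}

.new_selection_result <- function(method, selected, best_sets, best_crit, names_all, k) {
  structure(
    list(
      method = method,
      selected_indices = selected,
      selected_names = names_all[selected],
      criterion_by_size = best_crit,
      subsets_by_size = best_sets,
      chosen_size = length(selected),
      k = k,
      feature_names = names_all
    ),
    class = "selection_result"
  )
}

#' Sequential forward selection (SFS)
#'
#' Greedy forward search: starting from the empty set, at each step the
#' feature whose inclusion maximises [knn_separability()] is added (ties
#' broken towards the lowest feature index). The best subset of each size up
#' to `max_size` is recorded; the returned subset is the size with the
#' highest criterion.
#'
#' @inheritParams knn_separability
#' @param max_size Largest subset size to examine (between 1 and the number
#'   of features).
#' @return A `selection_result` with the chosen indices (into the feature
#'   columns of `data`), names, and the criterion value per subset size.
#' @export
sfs_select <- function(data, max_size, k = 1) {
  prep <- .selection_prep(data, k)
  x <- prep$x
  d <- ncol(x)
  max_size <- as.integer(max_size)
  if (max_size < 1L || max_size > d) stop("`max_size` must be in [1, d]", call. = FALSE)
  current <- integer(0)
  best_crit <- rep(NA_real_, max_size)
  best_sets <- vector("list", max_size)
  while (length(current) < max_size) {
    cand <- setdiff(seq_len(d), current)
    vals <- vapply(cand, function(f)
      .subset_criterion(x, prep$label_int, c(current, f), k), numeric(1))
    pick <- cand[which.max(vals)]
    current <- c(current, pick)
    s <- length(current)
    best_crit[s] <- max(vals)
    best_sets[[s]] <- sort(current)
  }
  chosen <- best_sets[[which.max(best_crit)]]
  .new_selection_result("sfs", chosen, best_sets, best_crit, colnames(x), k)
}

#' Sequential floating forward selection (SFFS)
#'
#' The floating variant of forward selection: after every inclusion the
#' search conditionally excludes features again as long as the exclusion
#' strictly improves on the best criterion known for the reduced size. The
#' best-per-size record is seeded with the plain forward (SFS) pass and
#' only ever updated upwards, so the floating criterion curve dominates
#' the SFS curve at every size by construction.
#'
#' @inheritParams sfs_select
#' @return A `selection_result`; `chosen_size` is the size whose recorded
#'   criterion is maximal.
#' @export
sffs_select <- function(data, max_size, k = 1) {
  prep <- .selection_prep(data, k)
  x <- prep$x
  d <- ncol(x)
  max_size <- as.integer(max_size)
  if (max_size < 1L || max_size > d) stop("`max_size` must be in [1, d]", call. = FALSE)
  base <- sfs_select(data, max_size, k = k)
  best_crit <- base$criterion_by_size
  best_sets <- base$subsets_by_size
  current <- integer(0)
  current_val <- -Inf
  while (length(current) < max_size) {
    # forward step
    cand <- setdiff(seq_len(d), current)
    vals <- vapply(cand, function(f)
      .subset_criterion(x, prep$label_int, c(current, f), k), numeric(1))
    pick <- cand[which.max(vals)]
    current <- sort(c(current, pick))
    current_val <- max(vals)
    s <- length(current)
    if (current_val > best_crit[s]) {
      best_crit[s] <- current_val
      best_sets[[s]] <- current
    }
    # floating backward steps
    while (length(current) > 2L) {
      s <- length(current)
      vals_rm <- vapply(seq_along(current), function(ii)
        .subset_criterion(x, prep$label_int, current[-ii], k), numeric(1))
      ii <- which.max(vals_rm)
      if (vals_rm[ii] > best_crit[s - 1L]) {
        current <- current[-ii]
        current_val <- vals_rm[ii]
        best_crit[s - 1L] <- current_val
        best_sets[[s - 1L]] <- current
      } else {
        break
      }
    }
  }
  filled <- which(is.finite(best_crit))
  best_crit[!is.finite(best_crit)] <- NA_real_
  chosen <- best_sets[[filled[which.max(best_crit[filled])]]]
  .new_selection_result("sffs", chosen, best_sets, best_crit, colnames(x), k)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method = %s, chosen size = %d (criterion %.4g)\n",
              x$method, x$chosen_size,
              x$criterion_by_size[x$chosen_size]))
  cat("selected:", paste(x$selected_names, collapse = ", "), "\n")
  invisible(x)
}

#' Keep only the selected feature columns of a feature table
#'
#' @param data A feature table (metadata columns are preserved).
#' @param selection A `selection_result`.
#' @param size Optional subset size: use the best subset of that size found
#'   during the search instead of the criterion-maximising one. Sizes the
#'   search never reached fall back to the largest recorded size.
#' @return `data` restricted to metadata plus selected features.
#' @export
apply_selection <- function(data, selection, size = NULL) {
  keep <- intersect(c(.meta_cols, selection_features(selection, size)), names(data))
  data[keep]
}

#' @rdname apply_selection
#' @return `selection_features()`: the selected feature names.
#' @export
selection_features <- function(selection, size = NULL) {
  stopifnot(inherits(selection, "selection_result"))
  if (is.null(size)) return(selection$selected_names)
  size <- as.integer(size)
  filled <- which(!vapply(selection$subsets_by_size, is.null, logical(1)))
  size <- max(min(size, max(filled)), min(filled))
  while (is.null(selection$subsets_by_size[[size]])) size <- size - 1L
  selection$feature_names[selection$subsets_by_size[[size]]]
}
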