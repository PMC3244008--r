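# Single-frame classifiers: probabilistic (naive Bayes, Gaussian mixture,
# Parzen) and geometric (nearest mean, k-NN).

.class_labels <- function(labels) {
  if (is.factor(labels)) levels(droplevels(labels)) else sort(unique(as.character(labels)))
}

.split_by_class <- function(data) {
  labels <- as.character(data$label)
  x <- feature_matrix(data)
  cls <- .class_labels(data$label)
  list(x = x, labels = labels, classes = cls,
       by_class = lapply(cls, function(cl) x[labels == cl, , drop = FALSE]))
}

#' Fit a probabilistic single-frame classifier
#'
#' Estimates one class-conditional density per activity from that class's
#' training frames only. Three density families are available:
#' `naive_bayes` (independent univariate Gaussians per feature), `gmm`
#' (an `M`-component multivariate Gaussian mixture; `M = 1` is the
#' closed-form sample mean and regularised sample covariance), and
#' `parzen` (a Gaussian product-kernel density over the stored training
#' vectors with per-dimension Silverman bandwidths).
#'
#' For `gmm` with `M = 1` each class covariance is shrunk towards the
#' pooled within-class covariance (regularised discriminant analysis) with
#' weight `d / (d + n_c)` and floored on the diagonal; with as few as
#' `K = 7` training frames per class in a 17-dimensional feature space the
#' raw per-class estimate is singular, and its collapsed directions would
#' otherwise dominate the decision rule through the log-determinant.
#'
#' @param train A data frame with a `label` column and feature columns.
#' @param method One of `"naive_bayes"`, `"gmm"`, `"parzen"`.
#' @param M Number of mixture components for `method = "gmm"`.
#' @param bandwidth Optional fixed Parzen bandwidth (scalar); default is
#'   Silverman's rule per class and dimension.
#' @param priors Optional named class prior probabilities; stored for use
#'   with `predict(..., use_prior = TRUE)`. Defaults to training class
#'   frequencies.
#' @param seed Seed for the EM initialisation when `M > 1`.
#' @return A `frame_classifier` object.
#' @seealso [classify_probabilistic()], [evaluate_classifier()]
#' @export
fit_probabilistic <- function(train, method = c("naive_bayes", "gmm", "parzen"),
                              M = 1, bandwidth = NULL, priors = NULL, seed = 1) {
  method <- match.arg(method)
  sp <- .split_by_class(train)
  small <- vapply(sp$by_class, nrow, integer(1))
  min_n <- if (method == "parzen") 1L else 2L
  if (any(small < min_n)) {
    stop(sprintf("classes with fewer than %d training instances: %s",
                 min_n, paste(sp$classes[small < min_n], collapse = ", ")),
         call. = FALSE)
  }
  models <- switch(
    method,
    naive_bayes = lapply(sp$by_class, function(Xc) {
      sds <- apply(Xc, 2, stats::sd)
      floor_sd <- 1e-3 * max(mean(sds[sds > 0]), 1e-6)
      list(means = colMeans(Xc), sds = pmax(sds, floor_sd))
    }),
    gmm = fit_class_gaussians(sp$x, sp$labels, sp$classes, M = M, seed = seed),
    parzen = lapply(sp$by_class, function(Xc) {
      h <- if (!is.null(bandwidth)) rep(bandwidth, ncol(Xc)) else
        apply(Xc, 2, function(v) {
          b <- tryCatch(stats::bw.nrd0(v), error = function(e) NA_real_)
          if (!is.finite(b) || b <= 0) 1e-3 else b
        })
      list(points = Xc, bandwidths = h)
    })
  )
  names(models) <- sp$classes
  priors <- priors %||% (table(factor(sp$labels, levels = sp$classes)) / length(sp$labels))
  structure(
    list(kind = "probabilistic", method = method, classes = sp$classes,
         models = models, M = M,
         priors = as.numeric(priors), d = ncol(sp$x),
         feature_names = colnames(sp$x)),
    class = "frame_classifier"
  )
}

#' Fit a geometric single-frame classifier
#'
#' `nearest_mean` stores one centroid per class and assigns a frame to the
#' class of its closest centroid (Euclidean distance); `knn` stores the
#' training set and takes a majority vote among the `k` nearest training
#' frames. Ties are broken towards the lowest class index.
#'
#' @inheritParams fit_probabilistic
#' @param method `"nearest_mean"` or `"knn"`.
#' @param k Neighbour count for `knn`.
#' @return A `frame_classifier` object.
#' @export
fit_geometric <- function(train, method = c("nearest_mean", "knn"), k = 1) {
  method <- match.arg(method)
  sp <- .split_by_class(train)
  if (nrow(sp$x) == 0L) stop("empty training set", call. = FALSE)
  # standardise so that large-scale features (energies) do not dominate the
  # Euclidean metric; constant features are neutralised
  center <- colMeans(sp$x)
  scale_ <- apply(sp$x, 2, stats::sd)
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  xs <- sweep(sweep(sp$x, 2L, center), 2L, scale_, `/`)
  by_class_s <- lapply(sp$classes, function(cl) xs[sp$labels == cl, , drop = FALSE])
  models <- switch(
    method,
    nearest_mean = list(centroids = do.call(rbind, lapply(by_class_s, colMeans))),
    knn = list(points = xs, labels = sp$labels, k = as.integer(k))
  )
  structure(
    list(kind = "geometric", method = method, classes = sp$classes,
         models = models, d = ncol(sp$x), feature_names = colnames(sp$x),
         center = center, scale = scale_),
    class = "frame_classifier"
  )
}

# log class-conditional densities, one column per class
.class_log_density <- function(object, X) {
  switch(
    object$method,
    naive_bayes = vapply(object$models, function(m) {
      rowSums(vapply(seq_along(m$means), function(j)
        stats::dnorm(X[, j], m$means[j], m$sds[j], log = TRUE),
        numeric(nrow(X))) |> rbind())
    }, numeric(nrow(X))) |> rbind(),
    gmm = vapply(object$models, function(m) gm_log_density(m, X),
                 numeric(nrow(X))) |> rbind(),
    parzen = vapply(object$models, function(m) {
      lh <- sum(log(m$bandwidths))
      n_tr <- nrow(m$points)
      vapply(seq_len(nrow(X)), function(i) {
        z <- sweep(m$points, 2L, X[i, ]) |> sweep(2L, m$bandwidths, `/`)
        logsumexp(-0.5 * rowSums(z^2)) -
          log(n_tr) - lh - 0.5 * ncol(X) * log(2 * pi)
      }, numeric(1))
    }, numeric(nrow(X))) |> rbind()
  )
}

#' Predict activity labels (and scores) for feature frames
#'
#' Probabilistic classifiers assign each frame to the class with the
#' maximum class-conditional density (maximum likelihood, no prior
#' weighting, unless `use_prior = TRUE`); geometric classifiers use
#' centroid distance or the k-NN majority vote. Ties are broken towards
#' the lowest class index.
#'
#' @param object A `frame_classifier`.
#' @param newdata A data frame of feature columns (a `label` column, if
#'   present, is ignored) or a numeric matrix.
#' @param type `"label"` for predicted labels, `"score"` for the full
#'   per-class score matrix (log densities or negative distances).
#' @param use_prior Add log class priors to the densities (probabilistic
#'   classifiers only).
#' @param ... Unused.
#' @return A character vector of labels, or a score matrix.
#' @export
predict.frame_classifier <- function(object, newdata, type = c("label", "score"),
                                     use_prior = FALSE, ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(X)) &&
      all(object$feature_names %in% colnames(X))) {
    X <- X[, object$feature_names, drop = FALSE]
  }
  if (ncol(X) != object$d) {
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 object$d, ncol(X)), call. = FALSE)
  }
  if (object$kind == "probabilistic") {
    scores <- .class_log_density(object, X)
    if (use_prior) scores <- sweep(scores, 2L, log(object$priors), `+`)
  } else if (object$kind == "geometric") {
    X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, `/`)
  }
  if (object$kind == "geometric" && object$method == "nearest_mean") {
    cen <- object$models$centroids
    scores <- -vapply(seq_len(nrow(cen)), function(ci)
      sqrt(rowSums(sweep(X, 2L, cen[ci, ])^2)), numeric(nrow(X))) |> rbind()
  } else if (object$kind == "geometric") {  # knn
    k <- object$models$k
    tr <- object$models$points
    tl <- object$models$labels
    scores <- t(vapply(seq_len(nrow(X)), function(i) {
      dd <- sqrt(colSums((t(tr) - X[i, ])^2))
      nn <- order(dd)[seq_len(min(k, length(dd)))]
      votes <- table(factor(tl[nn], levels = object$classes))
      as.numeric(votes)
    }, numeric(length(object$classes))))
  }
  colnames(scores) <- object$classes
  if (type == "score") return(scores)
  object$classes[apply(scores, 1L, which.max)]
}

#' @rdname predict.frame_classifier
#' @param model A fitted probabilistic `frame_classifier`.
#' @param x A single feature vector (or a one-row data frame/matrix).
#' @export
classify_probabilistic <- function(model, x, use_prior = FALSE) {
  stopifnot(model$kind == "probabilistic")
  predict(model, rbind(x), use_prior = use_prior)
}

#' @rdname predict.frame_classifier
#' @export
classify_geometric <- function(model, x) {
  stopifnot(model$kind == "geometric")
  predict(model, rbind(x))
}

#' @export
print.frame_classifier <- function(x, ...) {
  cat(sprintf("<frame_classifier> %s (%s), %d classes, d = %d\n",
              x$method, x$kind, length(x$classes), x$d))
  invisible(x)
}
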