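# JSON serialization of fitted models. All numbers are written at full
# precision; invariants are re-validated on load.

.mat_to_list <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
.list_to_mat <- function(l, colnames = NULL) {
  m <- do.call(rbind, lapply(l, as.numeric))
  if (!is.null(colnames)) colnames(m) <- colnames
  m
}

.gm_to_list <- function(e) {
  list(weights = unname(as.numeric(e$weights)),
       feature_names = colnames(e$means),
       means = .mat_to_list(e$means),
       covariances = lapply(e$covariances, .mat_to_list))
}

.gm_from_list <- function(l) {
  fn <- if (!is.null(l$feature_names)) as.character(unlist(l$feature_names)) else NULL
  new_gaussian_mixture(
    as.numeric(unlist(l$weights)),
    .list_to_mat(l$means, fn),
    lapply(l$covariances, .list_to_mat)
  )
}

.model_to_list <- function(model) {
  if (inherits(model, "omm")) {
    list(type = "omm", labels = model$labels,
         prior = unname(as.numeric(model$prior)),
         tpm = .mat_to_list(model$tpm))
  } else if (inherits(model, "chmm")) {
    list(type = "chmm", labels = model$omm$labels,
         prior = unname(as.numeric(model$omm$prior)),
         tpm = .mat_to_list(model$omm$tpm),
         emissions = lapply(model$emissions, .gm_to_list))
  } else if (inherits(model, "rejection_model")) {
    list(type = "rejection_model", threshold = model$threshold,
         score_rule = model$score_rule, sensitivity = model$sensitivity,
         specificity = model$specificity,
         roc = list(threshold = model$roc$threshold,
                    sensitivity = model$roc$sensitivity,
                    specificity = model$roc$specificity))
  } else if (inherits(model, "frame_classifier")) {
    ms <- switch(
      model$method,
      naive_bayes = lapply(model$models, function(m)
        list(means = unname(m$means), sds = unname(m$sds))),
      gmm = lapply(model$models, .gm_to_list),
      parzen = lapply(model$models, function(m)
        list(points = .mat_to_list(m$points), bandwidths = unname(m$bandwidths))),
      nearest_mean = NULL,
      knn = NULL
    )
    geo <- if (model$kind == "geometric") {
      if (model$method == "nearest_mean") {
        list(centroids = .mat_to_list(model$models$centroids))
      } else {
        list(points = .mat_to_list(model$models$points),
             labels = model$models$labels, k = model$models$k)
      }
    }
    list(type = "frame_classifier", kind = model$kind, method = model$method,
         classes = model$classes, d = model$d,
         feature_names = model$feature_names,
         M = model$M %||% 1L,
         priors = unname(as.numeric(model$priors %||% rep(NA_real_, 0))),
         center = unname(as.numeric(model$center %||% rep(NA_real_, 0))),
         scale = unname(as.numeric(model$scale %||% rep(NA_real_, 0))),
         models = ms %||% geo)
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"),
         call. = FALSE)
  }
}

.model_from_list <- function(obj) {
  type <- obj$type %||% stop("malformed model file: missing `type` field", call. = FALSE)
  if (type == "omm") {
    omm(as.character(unlist(obj$labels)), as.numeric(unlist(obj$prior)),
        .list_to_mat(obj$tpm))
  } else if (type == "chmm") {
    labels <- as.character(unlist(obj$labels))
    om <- omm(labels, as.numeric(unlist(obj$prior)), .list_to_mat(obj$tpm))
    chmm(om, lapply(obj$emissions, .gm_from_list))
  } else if (type == "rejection_model") {
    structure(
      list(threshold = obj$threshold, score_rule = obj$score_rule,
           sensitivity = obj$sensitivity, specificity = obj$specificity,
           roc = tibble::tibble(
             threshold = as.numeric(unlist(obj$roc$threshold)),
             sensitivity = as.numeric(unlist(obj$roc$sensitivity)),
             specificity = as.numeric(unlist(obj$roc$specificity)))),
      class = "rejection_model")
  } else if (type == "frame_classifier") {
    fn <- as.character(unlist(obj$feature_names))
    classes <- as.character(unlist(obj$classes))
    models <- switch(
      obj$method,
      naive_bayes = lapply(obj$models, function(m)
        list(means = stats::setNames(as.numeric(unlist(m$means)), fn),
             sds = stats::setNames(as.numeric(unlist(m$sds)), fn))),
      gmm = lapply(obj$models, .gm_from_list),
      parzen = lapply(obj$models, function(m)
        list(points = .list_to_mat(m$points, fn),
             bandwidths = as.numeric(unlist(m$bandwidths)))),
      nearest_mean = list(centroids = {
        cen <- .list_to_mat(obj$models$centroids, fn); rownames(cen) <- classes; cen
      }),
      knn = list(points = .list_to_mat(obj$models$points, fn),
                 labels = as.character(unlist(obj$models$labels)),
                 k = as.integer(obj$models$k))
    )
    if (obj$method %in% c("naive_bayes", "gmm", "parzen")) names(models) <- classes
    out <- list(kind = obj$kind, method = obj$method, classes = classes,
                models = models, M = obj$M,
                priors = as.numeric(unlist(obj$priors)),
                d = as.integer(obj$d), feature_names = fn)
    if (length(obj$center %||% NULL) > 0) {
      out$center <- stats::setNames(as.numeric(unlist(obj$center)), fn)
      out$scale <- stats::setNames(as.numeric(unlist(obj$scale)), fn)
    }
    structure(out, class = "frame_classifier")
  } else {
    stop("unsupported model type in file: ", type, call. = FALSE)
  }
}

#' Save or load a fitted model as JSON
#'
#' Supported classes: [omm()], [chmm()], [calibrate_threshold()] rejection
#' models and `frame_classifier` objects. Numbers are written at full
#' precision, so a save/load/save cycle is byte-identical; model invariants
#' (probability normalisation, row sums) are re-validated when loading and
#' a violation raises a descriptive error.
#'
#' @param model A supported model object.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the reconstructed model.
#' @export
save_model <- function(model, path) {
  jsonlite::write_json(.model_to_list(model), path,
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop(sprintf("cannot parse model file '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  .model_from_list(obj)
}
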