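# End-to-end evaluation pipeline: simulate -> extract features -> select ->
# train -> calibrate rejection -> decode -> evaluate.

#' Configuration of the evaluation pipeline
#'
#' Defaults mirror the package's reference scenario: the seven-activity
#' vocabulary driven by [seven_activity_omm()], 512-sample windows with 50%
#' overlap at 76.25 Hz, a pool of `N = 30` frames per activity, `K = 7`
#' training frames per class, `S = 20` test sentences of `T = 300` frames,
#' `P = 5` training sentences, single-Gaussian emissions (`M = 1`) and a
#' 1:3 garbage injection rate on the stress-test sentences.
#'
#' @param seed Master seed; every random stage derives its stream from it.
#' @param rate,width,overlap Signal and windowing parameters.
#' @param frames_per_class Library pool size N per activity.
#' @param train_frames_per_class Training frames K per class (single-frame
#'   classifiers and cHMM emissions).
#' @param n_frames Sentence length T.
#' @param n_experiments Number of test sentences S.
#' @param n_train_experiments Number of training sentences P (transition
#'   counting).
#' @param n_garbage_experiments How many of the test sentences are also
#'   evaluated with garbage injection.
#' @param mixture_components Gaussian mixture size M per state/class.
#' @param selection_method `"sffs"`, `"sfs"` or `"none"`.
#' @param max_subset Largest feature-subset size explored by selection.
#' @param subset_size Feature dimension used downstream: the best subset of
#'   this size found by the search (default 17; the k-NN ratio criterion's
#'   raw argmax tends to collapse onto a single dominant feature, so a
#'   fixed working dimension is the more robust default). `NULL` uses the
#'   criterion-maximising size.
#' @param knn_k Neighbour count of the selection criterion.
#' @param transition_smoothing Laplace smoothing added to the first-phase
#'   transition counts; avoids structural zeros (and hence impossible
#'   Viterbi paths) when the few training sentences do not exhibit every
#'   feasible transition.
#' @param garbage_ratio Spurious-per-genuine injection rate (max 1/3).
#' @param n_garbage_train Garbage frames used to calibrate the rejection
#'   threshold (an independent garbage sample is used for testing).
#' @param refine On-the-fly second-phase mode applied per test sentence:
#'   `"none"`, `"transitions_only"` or `"all"`.
#' @param refine_max_iter Iteration cap for on-the-fly refinement.
#' @param selection Optional precomputed `selection_result` to reuse.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, rate = 76.25, width = 512, overlap = 0.5,
                            frames_per_class = 30, train_frames_per_class = 7,
                            n_frames = 300, n_experiments = 20,
                            n_train_experiments = 5, n_garbage_experiments = 10,
                            mixture_components = 1,
                            selection_method = c("sffs", "sfs", "none"),
                            max_subset = 20, subset_size = 17, knn_k = 1,
                            transition_smoothing = 0.5,
                            garbage_ratio = 1 / 3, n_garbage_train = 60,
                            refine = c("none", "transitions_only", "all"),
                            refine_max_iter = 10, selection = NULL) {
  structure(
    list(seed = as.integer(seed), rate = rate, width = width, overlap = overlap,
         frames_per_class = frames_per_class,
         train_frames_per_class = train_frames_per_class,
         n_frames = n_frames, n_experiments = n_experiments,
         n_train_experiments = n_train_experiments,
         n_garbage_experiments = n_garbage_experiments,
         mixture_components = mixture_components,
         selection_method = match.arg(selection_method),
         max_subset = max_subset, subset_size = subset_size, knn_k = knn_k,
         transition_smoothing = transition_smoothing,
         garbage_ratio = garbage_ratio, n_garbage_train = n_garbage_train,
         refine = match.arg(refine), refine_max_iter = refine_max_iter,
         selection = selection),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields not present in the file keep their [pipeline_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Run the full evaluation pipeline
#'
#' Simulates the reference scenario end to end and reports, per condition,
#' the aggregated confusion matrix and per-frame accuracy:
#' * `clean_sequential` — the cHMM sequential classifier on clean
#'   sentences;
#' * `clean_single_gmm` / `clean_single_nm` — single-frame classifiers on
#'   the identical frames;
#' * `garbage_no_reject` — the sequential classifier on garbage-injected
#'   sentences without rejection (every spurious frame necessarily counts
#'   as an error);
#' * `garbage_with_reject` — the same sentences with the ROC-calibrated
#'   likelihood threshold screening frames before decoding.
#'
#' The report also carries the achieved rejection sensitivity/specificity
#' on the held-out garbage sentences, the feature-selection result and the
#' fitted models. Reruns with the same configuration are identical.
#'
#' @param config A [pipeline_config()].
#' @return An `activity_pipeline_report` list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cf <- config
  om <- seven_activity_omm()
  specs <- default_activity_specs()
  gspecs <- garbage_activity_specs()
  seeds <- cf$seed * 100L + seq_len(12L)

  train_lib <- build_frame_library(specs, cf$train_frames_per_class,
                                   rate = cf$rate, width = cf$width,
                                   overlap = cf$overlap, seed = seeds[1])
  pool_lib <- build_frame_library(specs, cf$frames_per_class,
                                  rate = cf$rate, width = cf$width,
                                  overlap = cf$overlap, seed = seeds[2])
  g_per_class <- ceiling(cf$n_garbage_train / length(gspecs))
  garbage_train <- build_frame_library(gspecs, g_per_class, rate = cf$rate,
                                       width = cf$width, overlap = cf$overlap,
                                       seed = seeds[3])
  garbage_test <- build_frame_library(gspecs, g_per_class, rate = cf$rate,
                                      width = cf$width, overlap = cf$overlap,
                                      seed = seeds[4])

  selection <- cf$selection
  if (is.null(selection) && cf$selection_method != "none") {
    selector <- if (cf$selection_method == "sffs") sffs_select else sfs_select
    selection <- selector(pool_lib, max_size = cf$max_subset, k = cf$knn_k)
  }
  pick <- function(tbl) {
    if (is.null(selection)) return(tbl)
    apply_selection(tbl, selection, size = cf$subset_size)
  }
  train_sel <- pick(train_lib)
  pool_sel <- pick(pool_lib)
  garbage_train_sel <- pick(garbage_train)
  garbage_test_sel <- pick(garbage_test)

  train_exps <- lapply(seq_len(cf$n_train_experiments), function(i)
    make_virtual_experiment(om, train_sel, cf$n_frames, seed = seeds[5] + i))
  hmm <- first_phase_train(train_exps, M = cf$mixture_components,
                           smoothing = cf$transition_smoothing,
                           emission_frames = train_sel, labels = om$labels)
  gmm_clf <- fit_probabilistic(train_sel, "gmm", M = cf$mixture_components)
  nm_clf <- fit_geometric(train_sel, "nearest_mean")

  inlier_scores <- frame_score(hmm, dplyr::bind_rows(
    lapply(train_exps, function(e) e[setdiff(names(e), "spurious")])))
  outlier_scores <- frame_score(hmm, garbage_train_sel)
  rejector <- calibrate_threshold(inlier_scores, outlier_scores)

  labels_all <- sort(c(om$labels, "SPURIOUS"))
  cm_seq <- cm_gmm <- cm_nm <- cm_norej <- cm_rej <- list()
  cm_norej_gen <- cm_rej_gen <- list()
  rej_tp <- rej_fn <- rej_tn <- rej_fp <- 0L
  for (i in seq_len(cf$n_experiments)) {
    exp_i <- make_virtual_experiment(om, pool_sel, cf$n_frames, seed = seeds[6] + i)
    truth <- exp_i$label
    path <- classify_sequence(hmm, exp_i, refine = cf$refine,
                              refine_max_iter = cf$refine_max_iter)
    cm_seq[[i]] <- confusion_matrix(truth, path, labels_all)
    cm_gmm[[i]] <- confusion_matrix(truth, predict(gmm_clf, exp_i), labels_all)
    cm_nm[[i]] <- confusion_matrix(truth, predict(nm_clf, exp_i), labels_all)
    if (i <= cf$n_garbage_experiments && cf$garbage_ratio > 0) {
      gexp <- inject_garbage(exp_i, garbage_test_sel, ratio = cf$garbage_ratio,
                             seed = seeds[7] + i)
      gtruth <- gexp$label
      genuine <- !gexp$spurious
      norej <- classify_sequence(hmm, gexp, refine = cf$refine,
                                 refine_max_iter = cf$refine_max_iter)
      cm_norej[[i]] <- confusion_matrix(gtruth, norej, labels_all)
      cm_norej_gen[[i]] <- confusion_matrix(gtruth[genuine], norej[genuine], labels_all)
      withrej <- classify_sequence(hmm, gexp, rejector = rejector,
                                   refine = cf$refine,
                                   refine_max_iter = cf$refine_max_iter)
      cm_rej[[i]] <- confusion_matrix(gtruth, withrej, labels_all)
      cm_rej_gen[[i]] <- confusion_matrix(gtruth[genuine], withrej[genuine], labels_all)
      rejected <- withrej == "SPURIOUS"
      rej_tp <- rej_tp + sum(rejected & gexp$spurious)
      rej_fn <- rej_fn + sum(!rejected & gexp$spurious)
      rej_fp <- rej_fp + sum(rejected & !gexp$spurious)
      rej_tn <- rej_tn + sum(!rejected & !gexp$spurious)
    }
  }

  agg <- list(
    clean_sequential = aggregate_confusions(cm_seq),
    clean_single_gmm = aggregate_confusions(cm_gmm),
    clean_single_nm = aggregate_confusions(cm_nm)
  )
  if (length(cm_norej) > 0L) {
    agg$garbage_no_reject <- aggregate_confusions(cm_norej)
    agg$garbage_with_reject <- aggregate_confusions(cm_rej)
    agg$garbage_no_reject_genuine <- aggregate_confusions(cm_norej_gen)
    agg$garbage_with_reject_genuine <- aggregate_confusions(cm_rej_gen)
  }
  accuracies <- tibble::tibble(
    condition = names(agg),
    accuracy = vapply(agg, accuracy, numeric(1)),
    n_frames = vapply(agg, function(cm) sum(cm$counts), numeric(1))
  )
  structure(
    list(config = cf, selection = selection, chmm = hmm,
         classifiers = list(gmm = gmm_clf, nearest_mean = nm_clf),
         rejection = rejector,
         rejection_test = list(
           sensitivity = if (rej_tp + rej_fn > 0) rej_tp / (rej_tp + rej_fn) else NA_real_,
           specificity = if (rej_tn + rej_fp > 0) rej_tn / (rej_tn + rej_fp) else NA_real_),
         confusions = agg, accuracies = accuracies),
    class = "activity_pipeline_report"
  )
}

#' @export
print.activity_pipeline_report <- function(x, ...) {
  cat("<activity_pipeline_report>\n")
  df <- as.data.frame(x$accuracies)
  df$accuracy <- sprintf("%.4f", df$accuracy)
  print(df, row.names = FALSE)
  rt <- x$rejection_test
  if (is.finite(rt$sensitivity %||% NA_real_)) {
    cat(sprintf("rejection on held-out garbage: sensitivity %.3f, specificity %.3f\n",
                rt$sensitivity, rt$specificity))
  }
  invisible(x)
}
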