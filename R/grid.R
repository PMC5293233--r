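# The experiment grid: feature-selection scheme x subset size x classifier,
# every cell evaluated on shared stratified folds, and the per-class
# sample-size sweep (learning curve).

.default_schemes <- c("expert", "ig", "chi2", "pearson", "fms", "igfs")
.default_sizes <- c("10", "20", "30", "40", "all")

#' Enumerate the experiment grid
#'
#' The default grid is 6 schemes x 5 subset sizes x 5 classifiers = 150
#' cells.
#'
#' @param schemes feature-selection scheme names.
#' @param sizes subset sizes, as character (\code{"10"}, ..., \code{"all"}).
#' @param classifiers classifier kinds.
#' @return data frame with one row per cell (scheme, size, classifier).
#' @export
grid_cells <- function(schemes = .default_schemes,
                       sizes = .default_sizes,
                       classifiers = .classifier_kinds) {
  expand.grid(scheme = schemes, size = sizes, classifier = classifiers,
              stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

.size_to_k <- function(size) {
  if (identical(size, "all")) "all" else as.integer(size)
}

.cell_id <- function(scheme, size, classifier)
  paste(scheme, size, classifier, sep = "|")

#' Run the full experiment grid
#'
#' For every (scheme, subset size, classifier) cell: builds the training
#' set (the expert scheme truncates each class lexicon at depth k; the
#' automated schemes take the top-k features of their ranking over the
#' master vocabulary), runs stratified cross-validation and evaluates. All
#' cells share the fold partition, which depends only on the labels and
#' the seed. Results stream to \code{out_dir/grid_results.csv} as they
#' complete, so an interrupted grid resumes where it stopped; per-cell
#' failures are recorded and the grid continues.
#'
#' @param corpus list of \code{processed_report}s.
#' @param lexicons named list of \code{\link{expert_feature_set}}s (needed
#'   when \code{"expert"} is among the schemes).
#' @param schemes,sizes,classifiers grid axes (see
#'   \code{\link{grid_cells}}).
#' @param folds number of CV folds (default 10).
#' @param seed integer seed shared by fold assignment and model fitting.
#' @param rare_threshold passed to
#'   \code{\link{build_master_feature_vector}}.
#' @param out_dir optional directory for streamed results; \code{NULL}
#'   keeps everything in memory.
#' @return data frame of class \code{grid_result}, one row per cell with
#'   the evaluation metrics and an \code{error} column (\code{NA} on
#'   success).
#' @export
run_experiment_grid <- function(corpus, lexicons = NULL,
                                schemes = .default_schemes,
                                sizes = .default_sizes,
                                classifiers = .classifier_kinds,
                                folds = 10L, seed = 1L,
                                rare_threshold = 2, out_dir = NULL) {
  if ("expert" %in% schemes && is.null(lexicons))
    stop("the 'expert' scheme requires lexicons")
  cells <- grid_cells(schemes, sizes, classifiers)
  out_file <- NULL
  done <- character(0)
  prev <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out_file <- file.path(out_dir, "grid_results.csv")
    if (file.exists(out_file)) {
      prev <- utils::read.csv(out_file, stringsAsFactors = FALSE)
      done <- .cell_id(prev$scheme, prev$size, prev$classifier)
    }
  }
  M <- build_master_feature_vector(corpus, rare_threshold)
  bow_full <- build_bow_dataset(corpus, M)
  rankings <- list()
  for (s in setdiff(unique(cells$scheme), "expert")) {
    rankings[[s]] <- if (s == "igfs")
      suppressWarnings(rank_features(bow_full, scheme = s, k = "all"))
    else rank_features(bow_full, scheme = s)
  }
  rows <- if (is.null(prev)) list() else list(prev)
  for (i in seq_len(nrow(cells))) {
    sc <- cells$scheme[i]; sz <- cells$size[i]; cl <- cells$classifier[i]
    if (.cell_id(sc, sz, cl) %in% done) next
    row <- data.frame(scheme = sc, size = sz, classifier = cl,
                      precision_M = NA_real_, recall_M = NA_real_,
                      f_measure_M = NA_real_, accuracy_avg = NA_real_,
                      accuracy = NA_real_, auc_mean = NA_real_,
                      train_time = NA_real_, error = NA_character_,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      k <- .size_to_k(sz)
      ds <- if (sc == "expert") {
        build_class_score_dataset(corpus, lexicons, k = k)
      } else {
        feats <- suppressWarnings(select_top_k(rankings[[sc]], k))
        build_bow_dataset(corpus, M, subset = feats, scheme = sc, k = k)
      }
      pred <- train_and_predict_cv(ds, classifier_spec(cl, seed = seed),
                                   folds = folds, seed = seed)
      evaluate_predictions(pred)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
    } else {
      row$precision_M <- res$precision_M
      row$recall_M <- res$recall_M
      row$f_measure_M <- res$f_measure_M
      row$accuracy_avg <- res$accuracy_avg
      row$accuracy <- res$accuracy
      row$auc_mean <- res$auc_mean
      row$train_time <- res$train_time
    }
    rows[[length(rows) + 1L]] <- row
    if (!is.null(out_file))
      utils::write.csv(do.call(rbind, rows), out_file, row.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("grid_result", "data.frame")
  out
}

#' Long-form export of a grid result
#'
#' @param grid a \code{grid_result}.
#' @param path output CSV path (one row per scheme/size/classifier/metric).
#' @return \code{path}, invisibly.
#' @export
write_grid_long_csv <- function(grid, path) {
  metrics <- c("precision_M", "recall_M", "f_measure_M",
               "accuracy_avg", "accuracy", "auc_mean", "train_time")
  long <- do.call(rbind, lapply(metrics, function(m)
    data.frame(scheme = grid$scheme, size = grid$size,
               classifier = grid$classifier, metric = m,
               value = grid[[m]], stringsAsFactors = FALSE)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Learning curve over per-class sample size
#'
#' Regenerates a synthetic corpus at each per-class size, runs the chosen
#' scheme and classifier under cross-validation, and reports the accuracy
#' at each size.
#'
#' @param config a \code{\link{synthetic_config}}; its class set and rates
#'   are held fixed while \code{reports_total} is swept.
#' @param sizes_per_class integer vector of reports per class.
#' @param spec a \code{\link{classifier_spec}} (default random forest).
#' @param scheme feature scheme (default \code{"expert"}).
#' @param k subset size (default \code{"all"}).
#' @param folds CV folds (default 10, reduced automatically for tiny
#'   corpora).
#' @return data frame (n_per_class, accuracy, f_measure_M).
#' @export
sample_size_sweep <- function(config, sizes_per_class,
                              spec = classifier_spec("rf"),
                              scheme = "expert", k = "all", folds = 10L) {
  rows <- lapply(sizes_per_class, function(n) {
    cfg <- config
    cfg$reports_total <- as.integer(n) * nrow(config$classes)
    sim <- generate_corpus(cfg)
    proc <- preprocess_corpus(sim$reports, dictionary = sim$dictionary)
    ds <- if (scheme == "expert") {
      build_class_score_dataset(proc, sim$lexicons, k = k)
    } else {
      M <- build_master_feature_vector(proc)
      feats <- suppressWarnings(
        select_top_k(rank_features(build_bow_dataset(proc, M),
                                   scheme = scheme), k))
      build_bow_dataset(proc, M, subset = feats, scheme = scheme, k = k)
    }
    pred <- suppressWarnings(
      train_and_predict_cv(ds, spec, folds = folds, seed = config$seed))
    ev <- evaluate_predictions(pred)
    data.frame(n_per_class = n, accuracy = ev$accuracy,
               f_measure_M = ev$f_measure_M)
  })
  do.call(rbind, rows)
}
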