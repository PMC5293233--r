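# Uniform contract over five classifier families under stratified k-fold
# cross-validation. Learner internals are delegated to established
# implementations (e1071, caret, rpart, randomForest); the multinomial
# naive Bayes event model on raw counts is the one learner authored here.
# The fold partition is a function of (labels, folds, seed) only, so every
# feature scheme evaluated on the same corpus shares identical folds.

.classifier_kinds <- c("nb", "svm", "knn", "dt", "rf")

#' Specify a classifier
#'
#' @param kind one of \code{"nb"} (multinomial naive Bayes, Laplace
#'   \code{alpha}), \code{"svm"} (linear-kernel SVM, probability scores),
#'   \code{"knn"} (k-nearest neighbour, Euclidean, default \code{k = 3}),
#'   \code{"dt"} (entropy-split pruned decision tree) or \code{"rf"}
#'   (random forest, default \code{ntree = 100},
#'   \code{mtry = floor(sqrt(p))}).
#' @param params named list of hyperparameter overrides (\code{alpha},
#'   \code{cost}, \code{k}, \code{cp}, \code{ntree}, \code{mtry}).
#' @param seed integer seed recorded in the spec and used when fitting.
#' @return object of class \code{classifier_spec}.
#' @export
classifier_spec <- function(kind, params = list(), seed = 1L) {
  kind <- match.arg(kind, .classifier_kinds)
  structure(list(kind = kind, params = params, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("<classifier_spec>", x$kind, " seed:", x$seed, "\n")
  invisible(x)
}

# ---- multinomial naive Bayes on raw counts --------------------------------

.fit_mnb <- function(x, y, alpha = 1) {
  lev <- levels(y)
  logprior <- log(table(y)[lev] / length(y))
  logcond <- t(vapply(lev, function(l) {
    cnt <- colSums(x[y == l, , drop = FALSE]) + alpha
    log(cnt / sum(cnt))
  }, numeric(ncol(x))))
  list(levels = lev, logprior = as.numeric(logprior), logcond = logcond)
}

.predict_mnb <- function(fit, x) {
  ll <- x %*% t(fit$logcond)
  ll <- sweep(ll, 2L, fit$logprior, `+`)
  ll <- ll - apply(ll, 1L, max)
  p <- exp(ll)
  p <- p / rowSums(p)
  colnames(p) <- fit$levels
  p
}

# ---- per-kind fit/score, returning a per-class score matrix ----------------

.fit_score <- function(spec, xtr, ytr, xte) {
  lev <- levels(ytr)
  prm <- spec$params
  p <- switch(spec$kind,
    nb = {
      fit <- .fit_mnb(xtr, ytr, alpha = prm$alpha %||% 1)
      .predict_mnb(fit, xte)
    },
    svm = {
      fit <- e1071::svm(xtr, ytr, kernel = "linear",
                        cost = prm$cost %||% 1, probability = TRUE,
                        scale = FALSE)
      pr <- stats::predict(fit, xte, probability = TRUE)
      attr(pr, "probabilities")[, lev, drop = FALSE]
    },
    knn = {
      fit <- caret::knn3(xtr, ytr, k = prm$k %||% 3L)
      stats::predict(fit, xte, type = "prob")[, lev, drop = FALSE]
    },
    dt = {
      df <- data.frame(.y = ytr, xtr, check.names = TRUE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          parms = list(split = "information"),
                          control = rpart::rpart.control(
                            cp = prm$cp %||% 0.01))
      nd <- data.frame(xte, check.names = TRUE)
      colnames(nd) <- colnames(df)[-1L]
      stats::predict(fit, nd, type = "prob")[, lev, drop = FALSE]
    },
    rf = {
      fit <- randomForest::randomForest(
        xtr, ytr, ntree = prm$ntree %||% 100L,
        mtry = prm$mtry %||% max(1L, floor(sqrt(ncol(xtr)))))
      stats::predict(fit, xte, type = "prob")[, lev, drop = FALSE]
    })
  p <- as.matrix(p)
  rownames(p) <- NULL
  p
}

#' Stratified cross-validation folds
#'
#' Assigns each report to a fold, stratifying by class: within each class
#' level the indices are shuffled under the seed and dealt round-robin.
#' The partition depends only on \code{(labels, folds, seed)}, never on the
#' features, so different feature schemes share folds.
#'
#' @param labels factor (or character) of class labels.
#' @param folds requested number of folds (default 10). If some class has
#'   fewer instances the fold count is reduced with a warning; a class with
#'   a single instance is an error (regenerate or enlarge the corpus).
#' @param seed integer seed.
#' @return integer vector of fold ids in \code{1..folds}, with the
#'   (possibly reduced) fold count as attribute \code{"folds"}.
#' @export
make_folds <- function(labels, folds = 10L, seed = 1L) {
  y <- as.factor(labels)
  cnt <- table(y)
  if (any(cnt < 2L))
    stop("class(es) with a single instance: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "),
         "; regenerate the corpus with more reports per class")
  if (min(cnt) < folds) {
    folds <- as.integer(min(cnt))
    warning("smallest class has ", min(cnt),
            " instances; reducing folds to ", folds)
  }
  fold <- integer(length(y))
  rng <- .new_rng(seed)
  for (l in levels(y)) {
    idx <- which(y == l)
    idx <- idx[.rng_sample(rng, length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  attr(fold, "folds") <- folds
  fold
}

# local RNG stream so fold assignment never disturbs (or is disturbed by)
# the caller's RNG state
.new_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                     globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  env
}

.rng_sample <- function(rng, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                     globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  out <- sample.int(n)
  rng$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  out
}

#' Out-of-fold predictions under stratified cross-validation
#'
#' Fits the classifier on the training folds and scores the held-out fold,
#' rotating over all folds; every report is predicted exactly once. The
#' per-class score matrix rows sum to 1 for probabilistic learners; SVM
#' scores are pairwise-coupled probabilities. Wall-clock training time is
#' accumulated over folds.
#'
#' @param dataset a \code{\link{training_dataset}}.
#' @param spec a \code{\link{classifier_spec}}.
#' @param folds number of folds (default 10).
#' @param seed seed controlling both the fold partition and model fitting;
#'   defaults to the spec's seed.
#' @return object of class \code{fold_predictions}: \code{report_ids},
#'   \code{fold}, \code{truth}, \code{predicted}, \code{scores} (reports x
#'   classes), \code{train_time} (seconds), \code{spec}.
#' @export
train_and_predict_cv <- function(dataset, spec, folds = 10L, seed = NULL) {
  stopifnot(inherits(dataset, "training_dataset"),
            inherits(spec, "classifier_spec"))
  if (is.null(seed)) seed <- spec$seed
  y <- droplevels(dataset$y)
  x <- dataset$x
  fold <- make_folds(y, folds, seed)
  nf <- attr(fold, "folds")
  scores <- matrix(NA_real_, nrow(x), nlevels(y),
                   dimnames = list(NULL, levels(y)))
  ttime <- 0
  for (f in seq_len(nf)) {
    te <- fold == f
    set.seed((seed + 1009L * f) %% .Machine$integer.max)
    t0 <- proc.time()[["elapsed"]]
    scores[te, ] <- .fit_score(spec, x[!te, , drop = FALSE], y[!te],
                               x[te, , drop = FALSE])
    ttime <- ttime + (proc.time()[["elapsed"]] - t0)
  }
  pred_idx <- apply(scores, 1L, which.max)
  structure(list(report_ids = dataset$report_ids, fold = as.integer(fold),
                 truth = y,
                 predicted = factor(levels(y)[pred_idx], levels = levels(y)),
                 scores = scores, train_time = ttime, spec = spec),
            class = "fold_predictions")
}

#' @export
print.fold_predictions <- function(x, ...) {
  cat("<fold_predictions>", length(x$truth), "reports |",
      max(x$fold), "folds | classifier:", x$spec$kind,
      sprintf("| accuracy: %.3f\n", mean(x$truth == x$predicted)))
  invisible(x)
}

#' Export out-of-fold predictions as CSV
#'
#' @param pred a \code{fold_predictions} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_predictions_csv <- function(pred, path) {
  df <- data.frame(report_id = pred$report_ids, fold = pred$fold,
                   true = pred$truth, predicted = pred$predicted,
                   check.names = FALSE)
  sc <- as.data.frame(pred$scores)
  names(sc) <- paste0("score_", names(sc))
  utils::write.csv(cbind(df, sc), path, row.names = FALSE)
  invisible(path)
}
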