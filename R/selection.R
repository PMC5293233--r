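# Automated filter feature selection over the bag-of-words representation.
#
# Five ranking schemes (information gain, chi-square, Pearson correlation,
# linear-kernel Fisher-Markov selector, and an information-gain/odds-ratio
# ensemble) plus gain ratio and a Borda rank-aggregation fusion baseline.
# Information gain, chi-square, gain ratio and the odds ratio operate on
# document-level presence/absence contingency tables; Pearson and the
# Fisher-Markov criterion operate on the raw per-report count vectors.
# All scorers break ties alphabetically, so rankings are deterministic and
# invariant to report and feature order.

.ranked <- function(features, scores, scheme, extra = NULL) {
  stopifnot(length(features) == length(scores))
  out <- data.frame(feature = features, score = as.numeric(scores),
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  out <- out[order(-out$score, out$feature), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "scheme") <- scheme
  class(out) <- c("ranked_features", "data.frame")
  out
}

.entropy2 <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# class-count table for presence (pres = logical vector) vs labels
.presence_split_gain <- function(pres, y, want_split_info = FALSE) {
  I <- .entropy2(table(y))
  n <- length(y)
  parts <- split(y, pres)
  after <- sum(vapply(parts, function(yy)
    length(yy) / n * .entropy2(table(yy)), numeric(1)))
  gain <- I - after
  if (!want_split_info) return(gain)
  si <- .entropy2(vapply(parts, length, numeric(1)))
  c(gain = gain, split_info = si)
}

#' Information-gain feature scores
#'
#' Scores each feature by the reduction in class entropy (base 2) obtained
#' by splitting the corpus on document-level presence/absence of the
#' feature: \eqn{Gain = I - \sum_v (n_v/n) I_v}, where \eqn{I} is the class
#' entropy \eqn{-\sum_c p_c \log_2 p_c} generalized to any number of
#' classes.
#'
#' @param x numeric count matrix (reports x features, named columns),
#'   e.g. from \code{\link{build_bow_dataset}}.
#' @param y factor of class labels.
#' @return a \code{ranked_features} data frame (feature, score, rank),
#'   sorted by score descending with alphabetical tie-break.
#' @export
score_information_gain <- function(x, y) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L)
    warning("single-class corpus: all information-gain scores are 0")
  s <- apply(x > 0, 2L, .presence_split_gain, y = y)
  .ranked(colnames(x), s, "ig")
}

#' Chi-square feature scores
#'
#' Scores each feature by \eqn{\chi^2 = \sum (O-E)^2/E} over the 2 x C
#' presence-by-class contingency table, with expected counts from the
#' marginal products. Cells with zero expected count contribute 0.
#'
#' @inheritParams score_information_gain
#' @return a \code{ranked_features} data frame.
#' @export
score_chi_square <- function(x, y) {
  y <- as.factor(y)
  s <- apply(x > 0, 2L, function(pres) {
    O <- table(factor(pres, levels = c(FALSE, TRUE)), y)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    cells <- E > 0
    sum((O[cells] - E[cells])^2 / E[cells])
  })
  .ranked(colnames(x), s, "chi2")
}

#' Pearson-correlation feature scores
#'
#' For each feature, computes the Pearson correlation between its
#' per-report count vector and each one-vs-rest 0/1 class indicator, and
#' scores the feature by the maximum absolute correlation over classes.
#' Zero-variance features score 0.
#'
#' @inheritParams score_information_gain
#' @return a \code{ranked_features} data frame.
#' @export
score_pearson <- function(x, y) {
  y <- as.factor(y)
  ind <- vapply(levels(y), function(l) as.numeric(y == l),
                numeric(length(y)))
  s <- apply(x, 2L, function(v) {
    if (stats::sd(v) == 0) return(0)
    r <- vapply(seq_len(ncol(ind)), function(j) {
      if (stats::sd(ind[, j]) == 0) return(0)
      stats::cor(v, ind[, j])
    }, numeric(1))
    max(abs(r))
  })
  .ranked(colnames(x), s, "pearson")
}

#' Fisher-Markov feature scores (linear kernel)
#'
#' Under the linear (degree-1 polynomial) kernel the Fisher-Markov
#' criterion decomposes coordinate-wise: each feature is scored by the
#' ratio of its between-class scatter \eqn{\sum_c n_c (\bar x_c - \bar x)^2}
#' to its pooled within-class scatter, regularized by \code{gamma} added to
#' the denominator. A feature with zero within-class scatter but distinct
#' class means scores \code{Inf}; if every feature has zero within-class
#' scatter the ranking falls back to between-class scatter with a warning.
#'
#' @inheritParams score_information_gain
#' @param gamma non-negative regularizer added to the within-class scatter
#'   (default 0: pure Fisher criterion).
#' @return a \code{ranked_features} data frame.
#' @export
score_fms <- function(x, y, gamma = 0) {
  y <- as.factor(y)
  stopifnot(nlevels(droplevels(y)) >= 2L)
  groups <- split(seq_along(y), y)
  bw <- t(apply(x, 2L, function(v) {
    mu <- mean(v)
    b <- sum(vapply(groups, function(g)
      length(g) * (mean(v[g]) - mu)^2, numeric(1)))
    w <- sum(vapply(groups, function(g)
      sum((v[g] - mean(v[g]))^2), numeric(1)))
    c(b, w)
  }))
  if (all(bw[, 2L] + gamma == 0)) {
    warning("zero within-class scatter everywhere; ",
            "ranking by between-class scatter")
    s <- bw[, 1L]
  } else {
    s <- ifelse(bw[, 1L] == 0, 0, bw[, 1L] / (bw[, 2L] + gamma))
  }
  .ranked(colnames(x), s, "fms")
}

#' Gain-ratio feature scores
#'
#' Information gain divided by the split information (entropy of the
#' presence/absence partition). Features with zero split information score
#' 0.
#'
#' @inheritParams score_information_gain
#' @return a \code{ranked_features} data frame.
#' @export
score_gain_ratio <- function(x, y) {
  y <- as.factor(y)
  s <- apply(x > 0, 2L, function(pres) {
    gs <- .presence_split_gain(pres, y, want_split_info = TRUE)
    if (gs[["split_info"]] == 0) 0 else gs[["gain"]] / gs[["split_info"]]
  })
  .ranked(colnames(x), s, "gain_ratio")
}

# smoothed one-vs-rest odds ratio (document presence), +0.5 Haldane
.odds_ratio <- function(pres, pos) {
  a <- sum(pres & pos) + 0.5   # present in class
  b <- sum(!pres & pos) + 0.5  # absent in class
  c <- sum(pres & !pos) + 0.5  # present elsewhere
  d <- sum(!pres & !pos) + 0.5 # absent elsewhere
  (a * d) / (b * c)
}

#' Information-gain / odds-ratio ensemble feature selection
#'
#' An ensemble of a global metric (information gain) and a one-sided local
#' metric (smoothed one-vs-rest odds ratio). Features are scored globally
#' by information gain; the final top-\code{k} set is filled class-by-class
#' in round-robin over the class levels, each class contributing its
#' highest-gain feature whose odds ratio marks it positive (OR > 1) for
#' that class, so every class is represented in the selected set when
#' possible. A class with no remaining positive feature contributes from
#' the global list (with a warning). Features beyond the selected set
#' follow in global information-gain order.
#'
#' @inheritParams score_information_gain
#' @param k size of the class-balanced selected set (\code{<=} number of
#'   features, or \code{"all"}).
#' @return a \code{ranked_features} data frame; column \code{ig} carries
#'   the global information-gain score, \code{score} encodes the final
#'   selection order.
#' @export
score_igfs <- function(x, y, k = "all") {
  y <- as.factor(y)
  p <- ncol(x)
  if (identical(k, "all")) k <- p
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= p)
  global <- score_information_gain(x, y)
  pres <- x[, global$feature, drop = FALSE] > 0
  # per-class ordered candidate lists (positive odds ratio, global IG order)
  pos_lists <- lapply(levels(y), function(l) {
    ors <- apply(pres, 2L, .odds_ratio, pos = y == l)
    global$feature[ors[global$feature] > 1]
  })
  names(pos_lists) <- levels(y)
  selected <- character(0)
  cls <- levels(y)
  ci <- 1L
  starved <- character(0)
  while (length(selected) < k) {
    l <- cls[ci]
    cand <- setdiff(pos_lists[[l]], selected)
    if (length(cand)) {
      selected <- c(selected, cand[1L])
    } else {
      starved <- union(starved, l)
      fallback <- setdiff(global$feature, selected)
      selected <- c(selected, fallback[1L])
    }
    ci <- ci %% length(cls) + 1L
  }
  if (length(starved))
    warning("class(es) with no positive odds-ratio feature left: ",
            paste(starved, collapse = ", "),
            "; filled from the global ranking")
  rest <- setdiff(global$feature, selected)
  order_all <- c(selected, rest)
  scores <- rev(seq_len(p))             # descending score encodes the order
  names(scores) <- order_all
  out <- .ranked(order_all, scores[order_all], "igfs",
                 extra = data.frame(ig = global$score[
                   match(order_all, global$feature)]))
  out
}

#' Borda rank-aggregation fusion of four filter rankings
#'
#' The ensemble multi-filter baseline: chi-square, information gain,
#' Pearson correlation and gain ratio rankings are fused by mean rank
#' (Borda aggregation); features with smaller mean rank come first, ties
#' broken alphabetically.
#'
#' @inheritParams score_information_gain
#' @return a \code{ranked_features} data frame; column \code{mean_rank}
#'   holds the fused mean rank.
#' @export
emffs_rank_aggregation <- function(x, y) {
  parts <- list(score_chi_square(x, y), score_information_gain(x, y),
                score_pearson(x, y), score_gain_ratio(x, y))
  feats <- sort(colnames(x))
  mr <- rowMeans(vapply(parts, function(r)
    r$rank[match(feats, r$feature)], numeric(length(feats))))
  out <- .ranked(feats, -mr, "emffs",
                 extra = data.frame(mean_rank = mr))
  out
}

#' Take the top-k prefix of a feature ranking
#'
#' @param ranking a \code{ranked_features} data frame.
#' @param k positive integer or \code{"all"}. Values larger than the
#'   vocabulary are clamped with a warning.
#' @return character vector of selected feature names, in rank order.
#' @export
select_top_k <- function(ranking, k = "all") {
  n <- nrow(ranking)
  if (identical(k, "all")) return(ranking$feature)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (k > n) {
    warning("k = ", k, " exceeds vocabulary size ", n, "; clamped")
    k <- n
  }
  ranking$feature[seq_len(k)]
}

#' Build the bag-of-words training set
#'
#' Occurrence-count matrix of the corpus over (a subset of) the master
#' vocabulary, plus the nominal label. This is baseline 1 and the
#' representation every automated ranking scheme consumes.
#'
#' @param corpus list of \code{processed_report}s.
#' @param M a \code{master_features} vocabulary.
#' @param subset character vector of feature names (must be a subset of
#'   \code{M$feature}); \code{NULL} uses the full vocabulary.
#' @param scheme,k provenance recorded on the dataset.
#' @return a \code{\link{training_dataset}} of raw counts.
#' @export
build_bow_dataset <- function(corpus, M, subset = NULL, scheme = "bow",
                              k = "all") {
  feats <- if (is.null(subset)) M$feature else subset
  stopifnot(all(feats %in% M$feature))
  x <- vapply(corpus, function(pr) {
    v <- numeric(length(feats))
    idx <- match(names(pr$tokens), feats)
    hit <- !is.na(idx)
    v[idx[hit]] <- pr$tokens[hit]
    v
  }, numeric(length(feats)))
  x <- if (length(feats) == 1L) matrix(x, ncol = 1L) else t(x)
  colnames(x) <- feats
  labels <- vapply(corpus, `[[`, character(1), "label")
  training_dataset(x, factor(labels, levels = sort(unique(labels))),
                   report_ids = vapply(corpus, `[[`, character(1),
                                       "report_id"),
                   scheme = scheme, k = k)
}

#' Rank the master vocabulary under a named scheme
#'
#' Convenience front-end dispatching to the individual scorers; consumes
#' the bag-of-words counts of the corpus over the master vocabulary.
#'
#' @param x count matrix (reports x features) or a \code{training_dataset}.
#' @param y class factor (ignored when \code{x} is a dataset).
#' @param scheme one of \code{"ig"}, \code{"chi2"}, \code{"pearson"},
#'   \code{"fms"}, \code{"igfs"}, \code{"gain_ratio"}, \code{"emffs"}.
#' @param ... passed on (e.g. \code{gamma} for \code{"fms"}, \code{k} for
#'   \code{"igfs"}).
#' @return a \code{ranked_features} data frame.
#' @export
rank_features <- function(x, y = NULL, scheme, ...) {
  if (inherits(x, "training_dataset")) { y <- x$y; x <- x$x }
  switch(scheme,
         ig = score_information_gain(x, y),
         chi2 = score_chi_square(x, y),
         pearson = score_pearson(x, y),
         fms = score_fms(x, y, ...),
         igfs = score_igfs(x, y, ...),
         gain_ratio = score_gain_ratio(x, y),
         emffs = emffs_rank_aggregation(x, y),
         stop("unknown scheme: ", scheme))
}

#' Write feature rankings as CSV
#'
#' @param ranking a \code{ranked_features} data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_ranking_csv <- function(ranking, path) {
  df <- data.frame(feature = ranking$feature,
                   scheme = attr(ranking, "scheme") %||% "unknown",
                   score = ranking$score, rank = ranking$rank)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
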