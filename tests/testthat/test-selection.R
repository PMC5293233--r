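# helper: count matrix from a presence specification
counts_from_presence <- function(pres) {
  x <- matrix(as.numeric(pres), nrow = nrow(pres),
              dimnames = dimnames(pres))
  x
}

test_that("information gain matches the entropy identities", {
  # perfect split, balanced two classes: gain = class entropy = 1 bit
  y <- factor(rep(c("H", "M"), each = 4))
  x <- matrix(c(rep(1, 4), rep(0, 4)), ncol = 1,
              dimnames = list(NULL, "skull/Noun"))
  r <- score_information_gain(x, y)
  expect_equal(r$score, 1)
  # feature present in exactly half of each class: gain = 0
  x2 <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0), ncol = 1,
               dimnames = list(NULL, "f"))
  expect_equal(score_information_gain(x2, y)$score, 0)
  # single-class corpus warns and scores 0
  expect_warning(r1 <- score_information_gain(x, factor(rep("H", 8))),
                 "single-class")
  expect_equal(r1$score, 0)
})

test_that("chi-square matches hand-computed contingency values", {
  # O = [[10,0],[0,10]] with uniform margins: E = 5 everywhere, chi2 = 20
  y <- factor(rep(c("H", "M"), each = 10))
  x <- matrix(c(rep(1, 10), rep(0, 10)), ncol = 1,
              dimnames = list(NULL, "skull"))
  expect_equal(score_chi_square(x, y)$score, 20)
  # observed equal to expected in every cell: chi2 = 0
  x0 <- matrix(rep(c(1, 0), 10), ncol = 1, dimnames = list(NULL, "f"))
  expect_equal(score_chi_square(x0, y)$score, 0)
  # invariant to class label permutation
  y2 <- factor(rep(c("M", "H"), each = 10))
  expect_equal(score_chi_square(x, y)$score, score_chi_square(x, y2)$score)
})

test_that("Pearson scores are max |r| over one-vs-rest indicators", {
  y <- factor(c("A", "A", "B", "B", "B", "A"))
  ind <- matrix(as.numeric(y == "A"), ncol = 1,
                dimnames = list(NULL, "marker"))
  expect_equal(score_pearson(ind, y)$score, 1)
  const <- matrix(3, 6, 1, dimnames = list(NULL, "const"))
  expect_equal(score_pearson(const, y)$score, 0)
  # small fixture against the textbook formula
  set.seed(5)
  x <- matrix(rpois(18, 2), 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  r <- score_pearson(x, y)
  o <- oracle_pearson(x, y)
  expect_equal(r$score[match(names(o), r$feature)], unname(o))
})

test_that("the linear-kernel Fisher criterion ranks separating features first", {
  y <- factor(rep(c("A", "B"), each = 3))
  x <- cbind(sep = c(2, 2, 2, 5, 5, 5),      # zero within-class scatter
             noisy = c(1, 3, 2, 2, 4, 3),    # some separation
             flat = c(1, 2, 3, 1, 2, 3))     # identical distribution
  r <- score_fms(x, y)
  expect_equal(r$feature[1], "sep")
  expect_true(r$score[r$feature == "flat"] <=
                r$score[r$feature == "noisy"])
  # ordering matches exhaustive evaluation of the criterion
  o <- oracle_fms(x, y)
  expect_equal(order(-r$score[match(names(o), r$feature)]),
               order(-o))
  # degenerate: all features constant within class
  xd <- cbind(a = c(1, 1, 1, 2, 2, 2), b = c(0, 0, 0, 9, 9, 9))
  expect_warning(rd <- score_fms(xd * 0, y), "between-class")
})

test_that("gain ratio is gain over split information", {
  y <- factor(rep(c("A", "B"), each = 4))
  x <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), ncol = 1,
              dimnames = list(NULL, "f"))
  expect_equal(score_gain_ratio(x, y)$score, 1)  # gain 1 / split-info 1
  # feature present everywhere: split info 0, score 0 by convention
  xa <- matrix(1, 8, 1, dimnames = list(NULL, "f"))
  expect_equal(score_gain_ratio(xa, y)$score, 0)
})

test_that("igfs balances classes in round-robin and honours k", {
  # one perfect marker per class, k = 2: both markers selected
  y <- factor(rep(c("A", "B"), each = 4))
  x <- cbind(mA = c(1, 1, 1, 1, 0, 0, 0, 0),
             mB = c(0, 0, 0, 0, 1, 1, 1, 1),
             junk = c(1, 0, 1, 0, 1, 0, 1, 0))
  r <- score_igfs(x, y, k = 2)
  expect_setequal(r$feature[1:2], c("mA", "mB"))
  # k = vocabulary size selects everything (some class necessarily runs out
  # of positive-odds-ratio features and falls back to the global list)
  r_all <- suppressWarnings(score_igfs(x, y, k = "all"))
  expect_setequal(r_all$feature, colnames(x))
  expect_equal(nrow(r_all), 3)

  # 3-class fixture equals an independent simulation of the rule
  set.seed(9)
  y3 <- factor(rep(c("A", "B", "C"), each = 4))
  x3 <- matrix(rpois(12 * 6, 1), 12, 6,
               dimnames = list(NULL, paste0("f", 1:6)))
  k <- 4
  r3 <- score_igfs(x3, y3, k = k)
  # manual trace: global IG order, then per-class positive-OR lists
  ig <- oracle_ig(x3, y3)
  glob <- names(sort(ig, decreasing = TRUE))
  glob <- glob[order(-ig[glob], glob)]
  or_of <- function(f, cl) {
    pres <- x3[, f] > 0; pos <- y3 == cl
    ((sum(pres & pos) + .5) * (sum(!pres & !pos) + .5)) /
      ((sum(!pres & pos) + .5) * (sum(pres & !pos) + .5))
  }
  sel <- character(0); ci <- 1; cls <- levels(y3)
  while (length(sel) < k) {
    cand <- setdiff(glob[vapply(glob, or_of, 0, cl = cls[ci]) > 1], sel)
    sel <- c(sel, if (length(cand)) cand[1] else setdiff(glob, sel)[1])
    ci <- ci %% 3 + 1
  }
  expect_equal(r3$feature[1:k], sel)
})

test_that("rank-aggregation fusion reproduces hand-computed Borda order", {
  y <- factor(c("A", "A", "A", "B", "B", "B"))
  set.seed(31)
  x <- matrix(rpois(30, 2), 6, 5,
              dimnames = list(NULL, c("aa", "bb", "cc", "dd", "ee")))
  fused <- emffs_rank_aggregation(x, y)
  parts <- list(oracle_chi2(x, y), oracle_ig(x, y), oracle_pearson(x, y),
                oracle_gain_ratio(x, y))
  rank_of <- function(s) {
    feats <- names(s)
    ord <- feats[order(-s, feats)]
    stats::setNames(seq_along(ord), ord)[feats]
  }
  mean_rank <- rowMeans(vapply(parts, rank_of, numeric(5)))
  expected <- names(mean_rank)[order(mean_rank, names(mean_rank))]
  expect_equal(fused$feature, expected)
  expect_equal(fused$mean_rank[match(names(mean_rank), fused$feature)],
               unname(mean_rank))
  # unanimity: a feature ranked first by all four schemes stays first
  xu <- cbind(top = c(5, 6, 7, 0, 0, 0), x[, -1])
  fu <- emffs_rank_aggregation(xu, y)
  expect_equal(fu$feature[1], "top")
})

test_that("top-k selection is a prefix chain and clamps politely", {
  set.seed(3)
  fx <- random_fixture(3)
  r <- score_information_gain(fx$x, fx$y)
  for (j in seq_len(nrow(r) - 1))
    expect_equal(select_top_k(r, j), select_top_k(r, j + 1)[seq_len(j)])
  expect_equal(select_top_k(r, "all"), r$feature)
  expect_warning(full <- select_top_k(r, nrow(r) + 10), "clamped")
  expect_equal(full, r$feature)
})

test_that("every scorer equals its brute-force oracle on random fixtures", {
  for (seed in 1:30) {
    fx <- random_fixture(seed, max_reports = 16, max_feats = 8)
    checks <- list(
      list(score_information_gain(fx$x, fx$y), oracle_ig(fx$x, fx$y)),
      list(score_chi_square(fx$x, fx$y), oracle_chi2(fx$x, fx$y)),
      list(score_pearson(fx$x, fx$y), oracle_pearson(fx$x, fx$y)),
      list(score_fms(fx$x, fx$y), oracle_fms(fx$x, fx$y)),
      list(score_gain_ratio(fx$x, fx$y), oracle_gain_ratio(fx$x, fx$y)))
    for (ch in checks) {
      got <- ch[[1]]; want <- ch[[2]]
      expect_equal(got$score[match(names(want), got$feature)],
                   unname(want), tolerance = 1e-12)
    }
  }
})

test_that("scorers are invariant to report order and feature order", {
  fx <- random_fixture(77)
  perm_r <- sample(nrow(fx$x))
  perm_f <- sample(ncol(fx$x))
  for (scheme in c("ig", "chi2", "pearson", "fms", "gain_ratio", "emffs")) {
    a <- rank_features(fx$x, fx$y, scheme)
    b <- rank_features(fx$x[perm_r, , drop = FALSE], fx$y[perm_r], scheme)
    c_ <- rank_features(fx$x[, perm_f, drop = FALSE], fx$y, scheme)
    expect_equal(a$feature, b$feature)
    expect_equal(a$feature, c_$feature)
  }
})

test_that("score ranges hold: IG in [0, log2 C], chi2 >= 0, Pearson in [0,1]", {
  for (seed in 101:110) {
    fx <- random_fixture(seed, n_classes = 4)
    C <- nlevels(fx$y)
    expect_true(all(score_information_gain(fx$x, fx$y)$score >= -1e-12))
    expect_true(all(score_information_gain(fx$x, fx$y)$score <=
                      log2(C) + 1e-12))
    expect_true(all(score_chi_square(fx$x, fx$y)$score >= 0))
    p <- score_pearson(fx$x, fx$y)$score
    expect_true(all(p >= 0 & p <= 1 + 1e-12))
  }
})

test_that("bag-of-words datasets carry exact counts over the vocabulary", {
  corpus <- list(proc_from_tokens(c("skull", "skull", "liver"), "a", "A"),
                 proc_from_tokens(c("liver"), "b", "B"),
                 proc_from_tokens(character(0), "c", "B"))
  M <- build_master_feature_vector(corpus, rare_threshold = 0)
  ds <- build_bow_dataset(corpus, M)
  expect_equal(dim(ds$x), c(3L, nrow(M)))
  expect_equal(unname(ds$x[1, "skull/Noun"]), 2)
  expect_equal(unname(ds$x[2, "liver/Noun"]), 1)
  expect_equal(unname(ds$x[3, ]), rep(0, nrow(M)))  # empty report: zeros
  # counts match a naive recount
  for (i in 1:3) for (f in M$feature) {
    cnt <- corpus[[i]]$tokens[f]
    expect_equal(unname(ds$x[i, f]), unname(ifelse(is.na(cnt), 0, cnt)))
  }
  # subsetting keeps column order of the subset
  sub <- build_bow_dataset(corpus, M, subset = c("liver/Noun"))
  expect_equal(colnames(sub$x), "liver/Noun")
})
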