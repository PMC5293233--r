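# Independent brute-force oracles. Everything here is written as plain
# loops straight from the defining formulas, deliberately sharing no code
# with the package implementations it checks.

oracle_entropy <- function(labels) {
  out <- 0
  for (l in unique(labels)) {
    p <- sum(labels == l) / length(labels)
    out <- out - p * log2(p)
  }
  out
}

# information gain of one presence vector, straight from the definition
oracle_ig_one <- function(pres, y) {
  I <- oracle_entropy(y)
  after <- 0
  for (v in unique(pres)) {
    sub <- y[pres == v]
    after <- after + length(sub) / length(y) * oracle_entropy(sub)
  }
  I - after
}

oracle_ig <- function(x, y) {
  vapply(colnames(x), function(f) oracle_ig_one(x[, f] > 0, y), numeric(1))
}

oracle_chi2 <- function(x, y) {
  cls <- sort(unique(as.character(y)))
  vapply(colnames(x), function(f) {
    pres <- x[, f] > 0
    total <- length(y)
    s <- 0
    for (v in c(TRUE, FALSE)) for (cl in cls) {
      O <- sum(pres == v & y == cl)
      E <- sum(pres == v) * sum(y == cl) / total
      if (E > 0) s <- s + (O - E)^2 / E
    }
    s
  }, numeric(1))
}

# textbook Pearson r computed with explicit sums
oracle_r <- function(xv, yv) {
  n <- length(xv)
  sx <- sqrt(sum((xv - mean(xv))^2) / (n - 1))
  sy <- sqrt(sum((yv - mean(yv))^2) / (n - 1))
  if (sx == 0 || sy == 0) return(0)
  sum((xv - mean(xv)) * (yv - mean(yv))) / ((n - 1) * sx * sy)
}

oracle_pearson <- function(x, y) {
  cls <- sort(unique(as.character(y)))
  vapply(colnames(x), function(f) {
    best <- 0
    for (cl in cls) best <- max(best, abs(oracle_r(x[, f],
                                                   as.numeric(y == cl))))
    best
  }, numeric(1))
}

oracle_fms <- function(x, y, gamma = 0) {
  cls <- unique(as.character(y))
  vapply(colnames(x), function(f) {
    v <- x[, f]
    b <- 0; w <- 0
    for (cl in cls) {
      vc <- v[y == cl]
      b <- b + length(vc) * (mean(vc) - mean(v))^2
      w <- w + sum((vc - mean(vc))^2)
    }
    if (b == 0) 0 else b / (w + gamma)
  }, numeric(1))
}

oracle_gain_ratio <- function(x, y) {
  vapply(colnames(x), function(f) {
    pres <- x[, f] > 0
    si <- oracle_entropy(pres)
    if (si == 0) 0 else oracle_ig_one(pres, y) / si
  }, numeric(1))
}

# AUC as explicit counting of correctly ordered positive/negative pairs
oracle_auc_pairs <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  wins <- 0
  for (p in pos) for (q in neg) {
    if (p > q) wins <- wins + 1
    else if (p == q) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# naive scan: count occurrences of any top-k lexicon term in a token stream
oracle_expert_weight <- function(token_seq, E, k = "all") {
  n <- length(E$entries)
  kk <- if (identical(k, "all")) n else min(k, n)
  terms <- character(0)
  for (i in seq_len(kk))
    terms <- c(terms, E$entries[[i]]$canonical, E$entries[[i]]$synonyms)
  total <- 0
  for (tm in terms) {
    parts <- strsplit(tm, " ")[[1]]
    L <- length(parts)
    if (L == 1) {
      for (t in token_seq) if (t == tm) total <- total + 1
    } else if (length(token_seq) >= L) {
      for (s in 1:(length(token_seq) - L + 1))
        if (all(token_seq[s:(s + L - 1)] == parts)) total <- total + 1
    }
  }
  total
}

# random bag-of-words fixture with guaranteed >= 2 classes present
random_fixture <- function(seed, max_reports = 20, max_feats = 10,
                           n_classes = 3) {
  set.seed(seed)
  n <- sample(4:max_reports, 1)
  p <- sample(2:max_feats, 1)
  x <- matrix(rpois(n * p, 1.2), n, p,
              dimnames = list(NULL, paste0("f", sprintf("%02d", 1:p))))
  repeat {
    y <- factor(sample(paste0("C", 1:n_classes), n, replace = TRUE))
    if (nlevels(droplevels(y)) >= 2) break
  }
  list(x = x, y = droplevels(y))
}
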