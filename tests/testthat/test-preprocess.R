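test_that("spell correction fixes misspellings and leaves good text alone", {
  dict <- c("skull", "fracture", "noted")
  expect_equal(correct_spelling("skull fractur noted", dict),
               "skull fracture noted")
  expect_equal(correct_spelling("skull fracture noted", dict),
               "skull fracture noted")
  expect_equal(correct_spelling("", dict), "")
  # no candidate within distance 2 passes through unchanged
  expect_equal(correct_spelling("xylophone", dict), "xylophone")
})

test_that("spell correction tie-breaks are deterministic", {
  # "cot" is distance 1 from both; alphabetical tie-break picks "cat"
  expect_equal(correct_spelling("cot", c("cut", "cat")), "cat")
  # frequency outranks alphabetical order
  expect_equal(correct_spelling("cot", c(cat = 1, cut = 5)), "cut")
  # smaller edit distance always wins over frequency
  expect_equal(correct_spelling("cats", c(cat = 1, cut = 100)), "cat")
})

test_that("preprocessing lowercases, removes stopwords and tags tokens", {
  r <- report_from_text("The knee was bruised.")
  pr <- preprocess_report(r)
  expect_true("knee/Noun" %in% names(pr$tokens))
  expect_true("bruised/Verb" %in% names(pr$tokens))
  expect_false(any(c("the", "was") %in% pr$token_seq))
  expect_identical(pr$token_seq, tolower(pr$token_seq))
})

test_that("token multisets carry exact counts", {
  pr <- preprocess_report(report_from_text("abrasion abrasion laceration"))
  expect_equal(pr$tokens[["abrasion/Noun"]], 2L)
  expect_equal(pr$tokens[["laceration/Noun"]], 1L)
})

test_that("stopword-only and numeric/punctuation text yields empty output", {
  expect_warning(pr <- preprocess_report(report_from_text("the was of and")),
                 "no tokens")
  expect_length(pr$tokens, 0)
  expect_warning(pr2 <- preprocess_report(report_from_text("12 34 ;; 7.5")),
                 "no tokens")
  expect_length(pr2$token_seq, 0)
})

test_that("hyphenated terms stay single tokens and numerics are dropped", {
  pr <- preprocess_report(report_from_text(
    "postero-lateral abrasion measuring 5 cm"))
  expect_true("postero-lateral" %in% pr$token_seq)
  expect_false(any(grepl("^[0-9]", pr$token_seq)))
})

test_that("preprocessing is idempotent on clean stopword-free text", {
  txt <- "abrasion laceration skull fracture abrasion"
  p1 <- preprocess_report(report_from_text(txt))
  p2 <- preprocess_report(report_from_text(paste(p1$token_seq,
                                                 collapse = " ")))
  expect_identical(p1$tokens, p2$tokens)
})

test_that("outputs never contain stopwords or uppercase across fuzzed text", {
  sw <- default_stopwords()
  set.seed(42)
  words <- c(sw, "abrasion", "SKULL", "Bruise", "fracture", "Liver-Edge")
  for (i in 1:25) {
    txt <- paste(sample(words, 12, replace = TRUE), collapse = " ")
    pr <- suppressWarnings(preprocess_report(report_from_text(txt)))
    expect_false(any(pr$token_seq %in% sw))
    expect_identical(pr$token_seq, tolower(pr$token_seq))
  }
})

test_that("master feature vector prunes rare tokens and orders stably", {
  corpus <- list(
    proc_from_tokens(c("skull", "skull", "fracture"), "a", "A"),
    proc_from_tokens(c("skull", "skull", "xyz"), "b", "A"),
    proc_from_tokens(c("skull", "fracture", "fracture", "xyz"), "c", "B"))
  M <- build_master_feature_vector(corpus, rare_threshold = 2)
  expect_true("skull/Noun" %in% M$feature)       # 5 occurrences
  expect_true("fracture/Noun" %in% M$feature)    # 3 occurrences
  expect_false("xyz/Noun" %in% M$feature)        # 2 occurrences: pruned
  expect_equal(M$corpus_frequency[M$feature == "skull/Noun"], 5L)
  expect_equal(M$document_frequency[M$feature == "skull/Noun"], 3L)
  # threshold 0 keeps everything
  M0 <- build_master_feature_vector(corpus, rare_threshold = 0)
  expect_setequal(M0$feature, c("skull/Noun", "fracture/Noun", "xyz/Noun"))
  # permutation invariance
  M2 <- build_master_feature_vector(rev(corpus), rare_threshold = 2)
  expect_identical(M, M2)
  # descending frequency with alphabetical tie-break
  expect_false(is.unsorted(-M0$corpus_frequency))
})

test_that("document-level pruning counts reports, not occurrences", {
  corpus <- list(proc_from_tokens(rep("skull", 5), "a", "A"),
                 proc_from_tokens(c("fracture"), "b", "A"),
                 proc_from_tokens(c("fracture"), "c", "B"),
                 proc_from_tokens(c("fracture"), "d", "B"))
  Mc <- build_master_feature_vector(corpus, 2, prune_on = "corpus")
  Md <- build_master_feature_vector(corpus, 2, prune_on = "document")
  expect_true("skull/Noun" %in% Mc$feature)      # 5 total occurrences
  expect_false("skull/Noun" %in% Md$feature)     # but only 1 document
  expect_true("fracture/Noun" %in% Md$feature)   # 3 documents
})

test_that("demographics never influence downstream features", {
  base <- autopsy_report("r1", list(injury = "skull fracture abrasion"),
                         "S06", demographics = list(age = 30,
                                                    gender = "male"))
  mut <- autopsy_report("r1", list(injury = "skull fracture abrasion"),
                        "S06", demographics = list(age = 87,
                                                   gender = "female",
                                                   nationality = "malay"))
  other <- autopsy_report("r2", list(injury = "liver rupture rupture"),
                          "S36")
  lex <- list(S06 = simple_lexicon("S06", c("skull"), c("fracture")),
              S36 = simple_lexicon("S36", c("liver"), c("rupture")))
  both <- lapply(list(list(base, other), list(mut, other)), function(corpus) {
    proc <- preprocess_corpus(corpus)
    M <- build_master_feature_vector(proc, rare_threshold = 0)
    list(e = build_class_score_dataset(proc, lex)$x,
         b = build_bow_dataset(proc, M)$x)
  })
  expect_identical(both[[1]]$e, both[[2]]$e)
  expect_identical(both[[1]]$b, both[[2]]$b)
})

test_that("JSONL corpus round-trips and the directory loader reads labels", {
  reports <- list(
    autopsy_report("r1", list(injury = "skull fracture",
                              history = "fall from height"), "S06",
                   demographics = list(age = 41)),
    autopsy_report("r2", list(injury = "liver rupture"), "S36"))
  f <- tempfile(fileext = ".jsonl")
  write_corpus_jsonl(reports, f)
  back <- read_corpus_jsonl(f)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$sections$injury, "skull fracture")
  expect_equal(back[[1]]$label, "S06")
  expect_equal(back[[1]]$demographics$age, 41)

  d <- tempfile(); dir.create(d)
  writeLines(c("[injury]", "skull fracture", "[history]", "fall"),
             file.path(d, "r1.txt"))
  writeLines("liver rupture", file.path(d, "r2.txt"))
  labf <- tempfile(fileext = ".csv")
  writeLines(c("report_id,label", "r1,S06", "r2,S36"), labf)
  dirc <- read_corpus_dir(d, labf)
  expect_equal(dirc[[1]]$sections$injury, "skull fracture")
  expect_equal(dirc[[2]]$sections$history, "liver rupture")
  expect_equal(vapply(dirc, `[[`, "", "label"), c("S06", "S36"))
})
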