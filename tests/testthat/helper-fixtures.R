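# Small fixture builders used across the test files.

report_from_text <- function(text, id = "r1", label = "X",
                             demographics = list()) {
  autopsy_report(id, list(history = text), label,
                 demographics = demographics)
}

# a processed report built directly from a token sequence (surfaces only)
proc_from_tokens <- function(tokens, id = "r1", label = "X") {
  if (length(tokens) == 0) {
    counts <- integer(0)
    names(counts) <- character(0)
  } else {
    tagged <- paste0(tokens, "/", tag_tokens(tokens))
    tab <- table(tagged)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
  }
  structure(list(report_id = id, token_seq = tokens, tokens = counts,
                 label = label),
            class = "processed_report")
}

simple_lexicon <- function(class_code, ...) {
  groups <- list(...)
  entries <- lapply(seq_along(groups), function(i)
    list(canonical = groups[[i]][1], synonyms = groups[[i]][-1], rank = i))
  expert_feature_set(class_code, entries)
}

# small fast synthetic config for end-to-end tests
test_config <- function(n_per_class, seed, n_classes = 9, ...) {
  cls <- .default_mortcod_classes()[seq_len(n_classes), , drop = FALSE]
  cls$proportion <- rep(1 / n_classes, n_classes)
  synthetic_config(classes = cls,
                   reports_total = n_per_class * n_classes,
                   seed = seed, ...)
}

.default_mortcod_classes <- function() {
  data.frame(code = c("T07", "S06", "S38", "S17", "S28", "S36", "T71",
                      "T75", "G40"),
             proportion = c(260, 260, 260, 260, 250, 250, 220, 220, 220) /
               2200,
             stringsAsFactors = FALSE)
}
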