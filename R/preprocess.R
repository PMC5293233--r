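# Report preprocessing: spell correction, lowercasing, sentence splitting,
# unigram tokenization, stopword removal and coarse POS tagging, followed by
# construction of the corpus-wide master feature vector.

.section_order <- c("external_exam", "injury", "internal_exam",
                    "histopathology", "history")

.word_rx <- "[A-Za-z][A-Za-z'-]*"

#' Construct an autopsy report object
#'
#' @param report_id unique identifier string.
#' @param sections named list (or character vector) of free-text sections;
#'   canonical names are \code{external_exam}, \code{injury},
#'   \code{internal_exam}, \code{histopathology}, \code{history}. Unknown
#'   section names are kept and concatenated after the canonical ones.
#' @param label ICD-10 class code string.
#' @param demographics optional named list (age, gender, nationality, ...);
#'   carried through but never used as a feature.
#' @return object of class \code{autopsy_report}.
#' @export
autopsy_report <- function(report_id, sections, label, demographics = list()) {
  sections <- as.list(sections)
  if (length(sections) == 0L || all(!nzchar(unlist(sections))))
    stop("autopsy_report '", report_id, "': all sections are empty")
  if (is.null(names(sections)) || any(!nzchar(names(sections))))
    stop("autopsy_report '", report_id, "': sections must be named")
  structure(list(report_id = as.character(report_id),
                 sections = lapply(sections, as.character),
                 label = as.character(label),
                 demographics = demographics),
            class = "autopsy_report")
}

#' @export
print.autopsy_report <- function(x, ...) {
  cat("<autopsy_report>", x$report_id, " label:", x$label,
      " sections:", paste(names(x$sections), collapse = ", "), "\n")
  invisible(x)
}

# concatenate sections in the fixed canonical order; extra sections follow
# alphabetically so the result is independent of input ordering
.concat_sections <- function(sections) {
  known <- intersect(.section_order, names(sections))
  extra <- sort(setdiff(names(sections), .section_order))
  txt <- unlist(sections[c(known, extra)], use.names = FALSE)
  paste(txt[nzchar(txt)], collapse = ". ")
}

#' Deterministic dictionary-based spell correction
#'
#' Every word not found in the dictionary is replaced by the nearest
#' dictionary word within Levenshtein distance 2. Ties are broken by smallest
#' edit distance, then highest dictionary frequency, then alphabetically.
#' Out-of-dictionary words with no candidate within distance 2 pass through
#' unchanged, as do all in-dictionary words. Comparison is case-insensitive;
#' replacements are the dictionary form.
#'
#' @param text character scalar (or vector) of free text.
#' @param dictionary character vector of known words, or a numeric vector of
#'   word frequencies named by word.
#' @return corrected text, same shape as \code{text}.
#' @examples
#' correct_spelling("skull fractur noted", c("skull", "fracture", "noted"))
#' @export
correct_spelling <- function(text, dictionary) {
  stopifnot(length(dictionary) > 0L)
  if (is.numeric(dictionary)) {
    freq <- as.numeric(dictionary)
    words <- tolower(names(dictionary))
  } else {
    words <- tolower(as.character(dictionary))
    freq <- rep(1, length(words))
  }
  o <- order(words)          # alphabetical order makes ties resolve lexically
  words <- words[o]; freq <- freq[o]
  dup <- duplicated(words)
  words <- words[!dup]; freq <- freq[!dup]

  fix_one <- function(w) {
    lw <- tolower(w)
    if (lw %in% words) return(w)
    d <- utils::adist(lw, words)[1L, ]
    ok <- which(d <= 2L)
    if (length(ok) == 0L) return(w)
    best <- ok[d[ok] == min(d[ok])]
    best <- best[freq[best] == max(freq[best])]
    words[best[1L]]          # words sorted, so first = alphabetical tie-break
  }

  vapply(text, function(txt) {
    if (!nzchar(txt)) return(txt)
    m <- gregexpr(.word_rx, txt)
    toks <- regmatches(txt, m)[[1L]]
    if (length(toks) == 0L) return(txt)
    uniq <- unique(toks)
    repl <- vapply(uniq, fix_one, character(1))
    regmatches(txt, m) <- list(unname(repl[match(toks, uniq)]))
    txt
  }, character(1), USE.NAMES = FALSE)
}

.tokenize_words <- function(text) {
  # sentence split, then unigram word tokens; hyphenated clinical terms stay
  # single tokens; purely numeric and punctuation-only material never matches
  sentences <- unlist(strsplit(text, "[.!?;]+"))
  toks <- unlist(regmatches(sentences, gregexpr("[a-z][a-z'-]*", sentences)))
  toks[nzchar(toks)]
}

#' Preprocess one autopsy report
#'
#' Applies, in order: section concatenation (fixed order), spell correction,
#' lowercasing, sentence splitting and unigram tokenization, stopword
#' removal, and coarse POS tagging. Purely numeric and punctuation-only
#' tokens are dropped by the tokenizer. Demographics never enter the output.
#'
#' @param report an \code{\link{autopsy_report}}.
#' @param stoplist character vector of stopwords (lowercase).
#' @param dictionary optional spell-check dictionary (see
#'   \code{\link{correct_spelling}}); \code{NULL} skips correction.
#' @return object of class \code{processed_report}: \code{report_id},
#'   \code{token_seq} (ordered surfaces, pre-tagging, used for phrase
#'   matching), \code{tokens} (named integer multiset of "surface/Tag"
#'   counts), \code{label}.
#' @export
preprocess_report <- function(report, stoplist = default_stopwords(),
                              dictionary = NULL) {
  stopifnot(inherits(report, "autopsy_report"))
  text <- .concat_sections(report$sections)
  if (!is.null(dictionary)) text <- correct_spelling(text, dictionary)
  text <- tolower(text)
  toks <- .tokenize_words(text)
  toks <- toks[!(toks %in% tolower(stoplist))]
  if (length(toks) == 0L) {
    warning("report '", report$report_id, "': no tokens survive preprocessing")
    counts <- integer(0)
  } else {
    tagged <- paste0(toks, "/", tag_tokens(toks))
    tab <- table(tagged)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
  }
  structure(list(report_id = report$report_id, token_seq = toks,
                 tokens = counts, label = report$label),
            class = "processed_report")
}

#' Preprocess a corpus of reports
#'
#' @param corpus list of \code{\link{autopsy_report}} objects.
#' @inheritParams preprocess_report
#' @return list of \code{processed_report} objects, class
#'   \code{processed_corpus}.
#' @export
preprocess_corpus <- function(corpus, stoplist = default_stopwords(),
                              dictionary = NULL) {
  structure(lapply(corpus, preprocess_report, stoplist = stoplist,
                   dictionary = dictionary),
            class = "processed_corpus")
}

#' The vendored English stopword list
#'
#' @return character vector of stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "mortcod")
  readLines(path, warn = FALSE)
}

#' Build the corpus-wide master feature vector
#'
#' Tallies every distinct tagged token over the corpus and prunes rare
#' tokens. Ordering is deterministic: descending corpus frequency with
#' alphabetical tie-break, so the vocabulary is invariant to report order.
#'
#' @param corpus list of \code{processed_report}s.
#' @param rare_threshold tokens whose pruning count is \code{<=} this value
#'   are discarded (default 2, i.e. tokens appearing once or twice go).
#' @param prune_on \code{"corpus"} (total occurrences, default) or
#'   \code{"document"} (number of reports containing the token).
#' @return data.frame of class \code{master_features} with columns
#'   \code{feature} ("surface/Tag"), \code{surface}, \code{tag},
#'   \code{corpus_frequency}, \code{document_frequency}.
#' @export
build_master_feature_vector <- function(corpus, rare_threshold = 2,
                                        prune_on = c("corpus", "document")) {
  stopifnot(length(corpus) > 0L)
  prune_on <- match.arg(prune_on)
  feat_all <- unlist(lapply(corpus, function(pr) names(pr$tokens)),
                     use.names = FALSE)
  cnt_all <- unlist(lapply(corpus, function(pr) unname(pr$tokens)),
                    use.names = FALSE)
  if (length(feat_all) == 0L) {
    warning("corpus contains no tokens; master feature vector is empty")
    out <- data.frame(feature = character(0), surface = character(0),
                      tag = character(0), corpus_frequency = integer(0),
                      document_frequency = integer(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("master_features", "data.frame")
    return(out)
  }
  cf <- tapply(cnt_all, feat_all, sum)
  df <- table(feat_all)
  feat <- names(cf)
  out <- data.frame(
    feature = feat,
    surface = sub("/[^/]*$", "", feat),
    tag = sub("^.*/", "", feat),
    corpus_frequency = as.integer(cf),
    document_frequency = as.integer(df[feat]),
    stringsAsFactors = FALSE)
  keep <- if (prune_on == "corpus") out$corpus_frequency > rare_threshold
          else out$document_frequency > rare_threshold
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$corpus_frequency, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("master_features", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
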