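# Expert-driven feature selection: per-class ranked lexicons with synonym
# groups, matched against each report's token stream to produce one
# frequency-count attribute per class. This is the package's core scheme:
# instead of ranking the corpus vocabulary, the discriminative terms are
# supplied (and ranked) by domain experts, so the resulting training set has
# exactly as many numeric attributes as there are classes.

#' Construct an expert feature set for one class
#'
#' @param class_code ICD-10 class code string.
#' @param entries list of entries, each a list with \code{canonical} (term
#'   string, possibly multi-word), optional \code{synonyms} (character
#'   vector) and \code{rank} (positive integer). Ranks must be unique and
#'   contiguous from 1; entries are stored in rank order.
#' @return object of class \code{expert_feature_set}.
#' @export
expert_feature_set <- function(class_code, entries) {
  stopifnot(is.character(class_code), length(class_code) == 1L)
  if (length(entries) == 0L)
    stop("expert feature set '", class_code, "': empty entry list")
  entries <- lapply(entries, function(e) {
    list(canonical = tolower(as.character(e$canonical)),
         synonyms = tolower(as.character(e$synonyms %||% character(0))),
         rank = as.integer(e$rank))
  })
  ranks <- vapply(entries, `[[`, integer(1), "rank")
  if (anyDuplicated(ranks))
    stop("expert feature set '", class_code, "': duplicate rank ",
         ranks[duplicated(ranks)][1L])
  if (!setequal(ranks, seq_along(entries)))
    stop("expert feature set '", class_code,
         "': ranks must be contiguous 1..", length(entries))
  entries <- entries[order(ranks)]
  terms <- unlist(lapply(entries, function(e) c(e$canonical, e$synonyms)))
  if (anyDuplicated(terms))
    stop("expert feature set '", class_code, "': term '",
         terms[duplicated(terms)][1L], "' appears in more than one entry")
  structure(list(class_code = class_code, entries = entries),
            class = "expert_feature_set")
}

#' @export
print.expert_feature_set <- function(x, ...) {
  cat("<expert_feature_set>", x$class_code, "-", length(x$entries),
      "ranked entries\n")
  invisible(x)
}

#' Load expert feature sets from a YAML lexicon file
#'
#' The file holds one document: a list of class blocks, each with
#' \code{class_code} and \code{entries} (ordered list of
#' \code{canonical}/\code{synonyms}/\code{rank}). A missing \code{synonyms}
#' key loads as an empty synonym group; a missing \code{rank} defaults to
#' the entry's position.
#'
#' @param path YAML file path.
#' @return named list of \code{\link{expert_feature_set}} objects, one per
#'   class, named by class code.
#' @export
load_expert_feature_sets <- function(path) {
  doc <- yaml::read_yaml(path)
  sets <- lapply(doc, function(cls) {
    if (is.null(cls$class_code)) stop("lexicon block without class_code")
    entries <- lapply(seq_along(cls$entries), function(i) {
      e <- cls$entries[[i]]
      if (is.null(e$rank)) e$rank <- i
      e
    })
    expert_feature_set(cls$class_code, entries)
  })
  codes <- vapply(sets, `[[`, character(1), "class_code")
  if (anyDuplicated(codes))
    stop("duplicate class code in lexicon file: ", codes[duplicated(codes)][1L])
  names(sets) <- codes
  sets
}

#' Write expert feature sets to a YAML lexicon file
#'
#' @param sets list of \code{\link{expert_feature_set}} objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_expert_feature_sets <- function(sets, path) {
  doc <- lapply(sets, function(s) {
    list(class_code = s$class_code,
         entries = lapply(s$entries, function(e)
           list(canonical = e$canonical, synonyms = as.list(e$synonyms),
                rank = e$rank)))
  })
  yaml::write_yaml(unname(doc), path)
  invisible(path)
}

# terms (canonical + synonyms) of the top-k entries, as token sequences
.topk_terms <- function(E, k) {
  n <- length(E$entries)
  k <- if (identical(k, "all")) n else min(as.integer(k), n)
  stopifnot(k >= 1L)
  terms <- unlist(lapply(E$entries[seq_len(k)], function(e)
    c(e$canonical, e$synonyms)), use.names = FALSE)
  strsplit(terms, "\\s+")
}

#' Expert-driven feature weight of a report for one class
#'
#' Counts, over the report's (pre-tagging) token stream, the occurrences of
#' any canonical term or synonym among the top-\code{k} ranked entries of the
#' class lexicon. Matching is on the surface form, ignoring the POS tag;
#' multi-word terms match as contiguous token runs.
#'
#' @param report a \code{processed_report}.
#' @param E an \code{\link{expert_feature_set}}.
#' @param k lexicon depth: positive integer or \code{"all"} (default).
#' @param binary if \code{TRUE}, count each matching term at most once
#'   (presence/absence) instead of total frequency.
#' @return non-negative integer match count.
#' @export
expert_feature_weight <- function(report, E, k = "all", binary = FALSE) {
  toks <- report$token_seq
  if (length(toks) == 0L) return(0L)
  terms <- .topk_terms(E, k)
  total <- 0L
  single <- unlist(terms[lengths(terms) == 1L], use.names = FALSE)
  if (length(single)) {
    hits <- toks %in% single
    if (binary) total <- total + length(unique(toks[hits]))
    else total <- total + sum(hits)
  }
  for (tm in terms[lengths(terms) > 1L]) {
    L <- length(tm)
    if (L > length(toks)) next
    starts <- which(toks == tm[1L])
    starts <- starts[starts + L - 1L <= length(toks)]
    nhit <- sum(vapply(starts, function(s)
      all(toks[s:(s + L - 1L)] == tm), logical(1)))
    total <- total + if (binary) as.integer(nhit > 0L) else nhit
  }
  as.integer(total)
}

#' Build the expert-driven class-score training set
#'
#' One row per report; one numeric attribute per class holding the Eq-style
#' frequency-count weight of the report against that class's lexicon
#' (truncated at depth \code{k}); the nominal label last. The attribute
#' count equals the number of classes regardless of vocabulary size.
#'
#' @param corpus list of \code{processed_report}s.
#' @param sets named list of \code{\link{expert_feature_set}}s covering
#'   every label occurring in the corpus.
#' @param k lexicon depth per class (integer or \code{"all"}).
#' @param binary passed to \code{\link{expert_feature_weight}}.
#' @return a \code{\link{training_dataset}} with scheme \code{"expert"}.
#' @export
build_class_score_dataset <- function(corpus, sets, k = "all",
                                      binary = FALSE) {
  codes <- unname(vapply(sets, `[[`, character(1), "class_code"))
  labels <- vapply(corpus, `[[`, character(1), "label")
  missing <- setdiff(unique(labels), codes)
  if (length(missing))
    stop("no expert feature set for label(s): ",
         paste(missing, collapse = ", "))
  x <- vapply(sets, function(E)
    vapply(corpus, expert_feature_weight, numeric(1), E = E, k = k,
           binary = binary),
    numeric(length(corpus)))
  x <- matrix(x, nrow = length(corpus),
              dimnames = list(NULL, codes))
  training_dataset(x, factor(labels, levels = sort(codes)),
                   report_ids = vapply(corpus, `[[`, character(1),
                                       "report_id"),
                   scheme = "expert", k = k)
}
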