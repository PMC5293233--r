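# Seeded synthetic autopsy-report corpus generator.
#
# Emulates the statistical structure the classification pipeline assumes
# rather than real clinical language: nine ICD-10 classes in fixed
# proportions, per-class ranked pools of discriminative terms with
# interchangeable synonym groups, a shared background vocabulary, short
# clinical-style section templates, and injected single-edit misspellings.
# Everything is a deterministic function of the config seed.

.default_classes <- data.frame(
  code = c("T07", "S06", "S38", "S17", "S28", "S36", "T71", "T75", "G40"),
  records = c(260, 260, 260, 260, 250, 250, 220, 220, 220),
  stringsAsFactors = FALSE)
.default_classes$proportion <- .default_classes$records /
  sum(.default_classes$records)

.syllables <- c("ab", "ra", "la", "ce", "to", "mi", "he", "pa", "cra", "ni",
                "fe", "mo", "lux", "or", "in", "ter", "os", "te", "ple",
                "ur", "vas", "cu", "lar", "men", "do", "sub", "du", "per",
                "fo", "gas", "tric", "bron", "chi", "ren", "tha", "lo",
                "sple", "no", "car", "di", "pul", "sa", "ly", "rup", "tu",
                "hae", "ma", "con", "tu", "sio")

.section_templates <- list(
  external_exam = c("external examination showed % and % over the % region",
                    "the body surface revealed % with adjacent %"),
  injury = c("there was a % with surrounding %",
             "a deep % involving the % and %"),
  internal_exam = c("internal examination revealed % of the %",
                    "dissection demonstrated % with % beneath the %"),
  histopathology = c("sections show % together with %"),
  history = c("history of % shortly before death"))

.template_words <- unique(unlist(
  regmatches(unlist(.section_templates),
             gregexpr("[a-z]+", unlist(.section_templates)))))

#' Configure the synthetic corpus generator
#'
#' Defaults describe a nine-class accident-mortality caseload: nine accident-related
#' ICD-10 classes (T07, S06, S38, S17, S28, S36, T71, T75, G40) whose
#' proportions are the exact record fractions 260/2200 (x4), 250/2200 (x2)
#' and 220/2200 (x3).
#'
#' @param classes data frame with columns \code{code} and
#'   \code{proportion} (proportions must sum to 1 within 1e-6; they are
#'   renormalized exactly).
#' @param reports_total total number of reports (default 2200).
#' @param n_terms discriminative lexicon entries per class (default 30).
#' @param synonym_group_size terms per synonym group, canonical included
#'   (default 3).
#' @param synonym_prob probability a drawn discriminative term surfaces as
#'   a synonym instead of its canonical form (default 0.5).
#' @param disc_rate Poisson mean of discriminative term draws per report
#'   (default 4); draws favour high-ranked entries geometrically.
#' @param background_vocab size of the background vocabulary shared by all
#'   classes (default 300).
#' @param background_rate Poisson mean of background term draws per report
#'   (default 40); draws follow 1/rank weights.
#' @param misspell_prob probability each content word is misspelled by one
#'   random single-character edit (default 0.03).
#' @param overlap fraction of each class's lexicon entries drawn from a
#'   pool shared across classes (default 0: disjoint class vocabularies).
#' @param sample_counts if \code{TRUE}, draw per-class report counts
#'   multinomially instead of the deterministic largest-remainder
#'   apportionment.
#' @param seed mandatory integer seed.
#' @return object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(classes = .default_classes,
                             reports_total = 2200L,
                             n_terms = 30L,
                             synonym_group_size = 3L,
                             synonym_prob = 0.5,
                             disc_rate = 4,
                             background_vocab = 300L,
                             background_rate = 40,
                             misspell_prob = 0.03,
                             overlap = 0,
                             sample_counts = FALSE,
                             seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(all(c("code", "proportion") %in% names(classes)),
            abs(sum(classes$proportion) - 1) < 1e-6,
            reports_total >= nrow(classes),
            synonym_prob >= 0, synonym_prob <= 1,
            misspell_prob >= 0, misspell_prob <= 1,
            overlap >= 0, overlap <= 1,
            synonym_group_size >= 1L)
  classes$proportion <- classes$proportion / sum(classes$proportion)
  structure(list(classes = classes,
                 reports_total = as.integer(reports_total),
                 n_terms = as.integer(n_terms),
                 synonym_group_size = as.integer(synonym_group_size),
                 synonym_prob = synonym_prob, disc_rate = disc_rate,
                 background_vocab = as.integer(background_vocab),
                 background_rate = background_rate,
                 misspell_prob = misspell_prob, overlap = overlap,
                 sample_counts = isTRUE(sample_counts),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# deterministic largest-remainder apportionment of total over proportions;
# remainder ties go to the earlier class
.apportion <- function(total, props) {
  quota <- total * props
  base <- floor(quota)
  rem <- quota - base
  left <- total - sum(base)
  if (left > 0) {
    give <- order(-rem, seq_along(rem))[seq_len(left)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

# unique pseudo-clinical words from syllables, avoiding stopwords and
# template words
.make_words <- function(n, taken = character(0)) {
  avoid <- c(taken, default_stopwords(), .template_words)
  out <- character(0)
  while (length(out) < n) {
    m <- (n - length(out)) * 2L
    w <- vapply(seq_len(m), function(i)
      paste(sample(.syllables, sample(3:4, 1L), replace = TRUE),
            collapse = ""), character(1))
    w <- w[nchar(w) >= 6L & !(w %in% avoid)]
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

.random_edit <- function(word) {
  letters_ <- letters
  i <- sample.int(nchar(word), 1L)
  op <- sample(c("sub", "del", "ins"), 1L)
  switch(op,
    sub = `substr<-`(word, i, i, sample(letters_, 1L)),
    del = paste0(substr(word, 1L, i - 1L),
                 substr(word, i + 1L, nchar(word))),
    ins = paste0(substr(word, 1L, i), sample(letters_, 1L),
                 substr(word, i + 1L, nchar(word))))
}

#' Generate per-class expert lexicons
#'
#' Builds, for each configured class, a ranked list of \code{n_terms}
#' discriminative entries, each a synonym group of
#' \code{synonym_group_size} generated pseudo-clinical terms. With
#' \code{overlap > 0} the last \code{round(overlap * n_terms)} entries of
#' every class come from a pool shared across classes. Resets the RNG to
#' the config seed, so the same config always yields the same lexicons.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return named list of \code{\link{expert_feature_set}}s.
#' @export
generate_lexicons <- function(config) {
  set.seed(config$seed)
  .generate_lexicons_here(config)
}

.generate_lexicons_here <- function(config) {
  ncls <- nrow(config$classes)
  n_shared <- round(config$overlap * config$n_terms)
  n_own <- config$n_terms - n_shared
  g <- config$synonym_group_size
  need <- ncls * n_own * g + n_shared * g
  pool <- .make_words(need)
  take <- function(k) {
    w <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    w
  }
  shared <- if (n_shared > 0)
    lapply(seq_len(n_shared), function(i) take(g)) else list()
  sets <- lapply(seq_len(ncls), function(ci) {
    own <- lapply(seq_len(n_own), function(i) take(g))
    groups <- c(own, shared)
    entries <- lapply(seq_along(groups), function(i)
      list(canonical = groups[[i]][1L],
           synonyms = groups[[i]][-1L], rank = i))
    expert_feature_set(config$classes$code[ci], entries)
  })
  names(sets) <- config$classes$code
  sets
}

#' Generate one synthetic autopsy report
#'
#' Draws a Poisson number of discriminative terms from the true class's
#' lexicon (rank-weighted geometrically, each surfacing as a uniformly
#' chosen synonym with the configured probability) and a Poisson number of
#' 1/rank-weighted background terms, shuffles them into short
#' clinical-style sentence templates across the five report sections, and
#' misspells each content word with the configured probability via a
#' single random character edit. Uses the current RNG stream unless
#' \code{seed} is given.
#'
#' @param class_code true class of the report.
#' @param lexicons named list of \code{\link{expert_feature_set}}s.
#' @param config a \code{\link{synthetic_config}}.
#' @param background character vector of background terms (ranked).
#' @param report_id identifier for the generated report.
#' @param seed optional integer seed for standalone reproducibility.
#' @return an \code{\link{autopsy_report}}.
#' @export
generate_report <- function(class_code, lexicons, config, background,
                            report_id = "r1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(class_code %in% names(lexicons))
  E <- lexicons[[class_code]]
  nE <- length(E$entries)
  n_disc <- stats::rpois(1L, config$disc_rate)
  disc <- character(0)
  if (n_disc > 0) {
    ranks <- sample.int(nE, n_disc, replace = TRUE, prob = 0.9^seq_len(nE))
    disc <- vapply(ranks, function(r) {
      e <- E$entries[[r]]
      if (length(e$synonyms) > 0 &&
          stats::runif(1L) < config$synonym_prob)
        sample(e$synonyms, 1L)
      else e$canonical
    }, character(1))
  }
  n_bg <- stats::rpois(1L, config$background_rate)
  bg <- if (n_bg > 0)
    sample(background, n_bg, replace = TRUE,
           prob = 1 / seq_along(background)) else character(0)
  content <- sample(c(disc, bg))
  if (config$misspell_prob > 0 && length(content) > 0) {
    hit <- stats::runif(length(content)) < config$misspell_prob
    content[hit] <- vapply(content[hit], .random_edit, character(1))
  }
  # deal content words into section sentence templates
  sections <- lapply(names(.section_templates), function(sec) {
    character(0)
  })
  names(sections) <- names(.section_templates)
  sec_names <- names(.section_templates)
  si <- 1L
  while (length(content) > 0) {
    sec <- sec_names[(si - 1L) %% length(sec_names) + 1L]
    tpl <- sample(.section_templates[[sec]], 1L)
    nslot <- lengths(regmatches(tpl, gregexpr("%", tpl)))
    fill <- content[seq_len(min(nslot, length(content)))]
    content <- content[-seq_len(length(fill))]
    fill <- c(fill, rep("finding", nslot - length(fill)))
    for (w in fill) tpl <- sub("%", w, tpl)
    sections[[sec]] <- c(sections[[sec]], tpl)
    si <- si + 1L
  }
  sections <- lapply(sections, function(s)
    if (length(s)) paste0(paste(s, collapse = ". "), ".") else "")
  sections <- sections[vapply(sections, nzchar, logical(1))]
  if (length(sections) == 0L) sections <- list(history = "no findings.")
  autopsy_report(report_id, sections, class_code,
                 demographics = list(
                   age = sample(5:90, 1L),
                   gender = sample(c("male", "female"), 1L),
                   nationality = sample(c("malay", "chinese", "indian",
                                          "indonesian", "pakistani"), 1L)))
}

#' Generate a labelled synthetic corpus with matching lexicons
#'
#' Per-class report counts follow deterministic largest-remainder
#' apportionment of \code{reports_total} over the class proportions (or a
#' multinomial draw when \code{sample_counts} is set). Returns the
#' ground-truth lexicons (the expert scheme's input) and the full
#' generator vocabulary as a spell-check dictionary.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with \code{reports} (list of
#'   \code{\link{autopsy_report}}s), \code{lexicons}, \code{dictionary}
#'   (character vector), \code{counts} (named per-class counts) and
#'   \code{config}.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  lexicons <- .generate_lexicons_here(config)
  background <- .make_words(config$background_vocab,
                            taken = unlist(lapply(lexicons, function(E)
                              unlist(E$entries))))
  counts <- if (config$sample_counts)
    as.integer(stats::rmultinom(1L, config$reports_total,
                                config$classes$proportion))
  else .apportion(config$reports_total, config$classes$proportion)
  names(counts) <- config$classes$code
  if (any(counts == 0))
    stop("reports_total too small: class(es) with zero reports")
  reports <- vector("list", sum(counts))
  idx <- 1L
  for (ci in seq_len(nrow(config$classes))) {
    code <- config$classes$code[ci]
    for (j in seq_len(counts[[code]])) {
      reports[[idx]] <- generate_report(
        code, lexicons, config, background,
        report_id = sprintf("r%05d", idx))
      idx <- idx + 1L
    }
  }
  dictionary <- sort(unique(c(
    unlist(lapply(lexicons, function(E) unlist(lapply(E$entries, function(e)
      c(e$canonical, e$synonyms))))),
    background, .template_words, "finding", "no", "findings")))
  list(reports = reports, lexicons = lexicons, dictionary = dictionary,
       counts = counts, config = config)
}
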