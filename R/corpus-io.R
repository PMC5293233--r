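# Corpus, word-list and lexicon file I/O.
#
# Interchange formats are deliberately plain text: JSON-lines for corpora
# (one report per line), one-entry-per-line word lists for the stoplist and
# spell dictionary, YAML for expert lexicons.

#' Read a JSON-lines corpus
#'
#' Each line is one report:
#' \code{\{"report_id", "sections": \{...\}, "label", "demographics": \{...\}\}}.
#'
#' @param path file path.
#' @return list of \code{\link{autopsy_report}} objects.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    autopsy_report(x$report_id, x$sections, x$label,
                   demographics = as.list(x$demographics))
  })
}

#' Write a corpus as JSON-lines
#'
#' @param corpus list of \code{\link{autopsy_report}} objects.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(corpus, function(r) {
    jsonlite::toJSON(list(report_id = r$report_id, sections = r$sections,
                          label = r$label, demographics = r$demographics),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a corpus from a directory of plain-text files
#'
#' One \code{.txt} file per report. Section headers are lines of the form
#' \code{[section_name]}; text before any header lands in the
#' \code{history} section. Labels come from a sidecar CSV with columns
#' \code{report_id,label}; report ids are file names without extension.
#'
#' @param dir directory containing \code{.txt} report files.
#' @param label_file path to the sidecar label CSV.
#' @return list of \code{\link{autopsy_report}} objects.
#' @export
read_corpus_dir <- function(dir, label_file) {
  labels <- utils::read.csv(label_file, stringsAsFactors = FALSE)
  stopifnot(all(c("report_id", "label") %in% names(labels)))
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(files, function(f) {
    id <- sub("\\.txt$", "", basename(f))
    row <- match(id, labels$report_id)
    if (is.na(row)) stop("no label for report '", id, "' in ", label_file)
    lines <- readLines(f, warn = FALSE)
    hdr <- grepl("^\\[[A-Za-z_]+\\]\\s*$", lines)
    sec <- cumsum(hdr)
    sec_names <- c("history", gsub("[][ ]", "", lines[hdr]))
    sections <- lapply(split(lines[!hdr], sec[!hdr]), paste, collapse = " ")
    names(sections) <- sec_names[as.integer(names(sections)) + 1L]
    sections <- sections[nzchar(trimws(unlist(sections)))]
    autopsy_report(id, sections, labels$label[row])
  })
}

#' Read a one-word-per-line word list
#'
#' Used for the stopword list and plain spell dictionaries. Lines may
#' optionally carry a frequency after whitespace (\code{word count}), in
#' which case a named numeric vector is returned.
#'
#' @param path file path.
#' @return character vector of words, or named numeric frequency vector.
#' @export
read_word_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  if (all(lengths(parts) == 1L)) return(unlist(parts))
  freq <- vapply(parts, function(p)
    if (length(p) > 1L) as.numeric(p[2L]) else 1, numeric(1))
  names(freq) <- vapply(parts, `[[`, character(1), 1L)
  freq
}

#' Write a word list, one entry per line
#'
#' @param words character vector (or named numeric frequency vector).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_word_list <- function(words, path) {
  if (is.numeric(words)) {
    writeLines(paste(names(words), words), path)
  } else {
    writeLines(words, path)
  }
  invisible(path)
}
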