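# Coarse lexical categorisation (POS tagging) over a closed five-tag set.
#
# A deterministic rule-based tagger is used: a small exception lexicon of
# common (mostly clinical-report) word forms, then suffix heuristics, with
# Noun as the default open-class tag. The coarse granularity is intentional:
# downstream feature names only need the "surface/Tag" rendering to be stable
# across runs and machines.

.mortcod_tagset <- c("Noun", "Verb", "Adjective", "Adverb", "Other")

# closed exception lexicon: irregular forms the suffix rules would mistag
.mortcod_tag_lexicon <- c(
  # verbs
  found = "Verb", seen = "Verb", shown = "Verb", show = "Verb",
  reveal = "Verb", sustain = "Verb", occur = "Verb", appear = "Verb",
  note = "Verb", observe = "Verb", contain = "Verb", extend = "Verb",
  measure = "Verb", weigh = "Verb", involve = "Verb", cause = "Verb",
  # adjectives
  multiple = "Adjective", severe = "Adjective", acute = "Adjective",
  large = "Adjective", small = "Adjective", deep = "Adjective",
  left = "Adjective", right = "Adjective", pale = "Adjective",
  extensive = "Adjective", bilateral = "Adjective", diffuse = "Adjective",
  subdural = "Adjective", irregular = "Adjective",
  # adverbs without -ly
  well = "Adverb", almost = "Adverb", quite = "Adverb"
)

#' Assign coarse lexical categories to tokens
#'
#' Maps each lowercase token to one of the closed tags \code{Noun},
#' \code{Verb}, \code{Adjective}, \code{Adverb} or \code{Other} using a fixed
#' exception lexicon followed by suffix rules (\code{-ly} adverb;
#' \code{-ed/-ing/-ise/-ize} verb; \code{-ous/-ful/-ive/-able/-ible/-ic/-al/-less}
#' adjective; default noun). Tokens containing no letter are tagged
#' \code{Other}. The mapping is a pure function of the surface form, so the
#' same token always receives the same tag.
#'
#' @param tokens character vector of lowercase word tokens.
#' @return character vector of tags, same length as \code{tokens}.
#' @examples
#' tag_tokens(c("knee", "bruised", "slowly", "severe"))
#' @export
tag_tokens <- function(tokens) {
  if (length(tokens) == 0L) return(character(0))
  stopifnot(is.character(tokens))
  tags <- rep("Noun", length(tokens))
  hit <- match(tokens, names(.mortcod_tag_lexicon))
  tags[!is.na(hit)] <- .mortcod_tag_lexicon[hit[!is.na(hit)]]
  rule <- is.na(hit)
  tags[rule & grepl("ly$", tokens)] <- "Adverb"
  tags[rule & grepl("(ed|ing|ise|ize)$", tokens) & nchar(tokens) > 4L] <- "Verb"
  tags[rule & grepl("(ous|ful|ive|able|ible|ic|al|less)$", tokens) &
         nchar(tokens) > 4L] <- "Adjective"
  tags[!grepl("[a-z]", tokens)] <- "Other"
  tags
}
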