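#' Tokenize mixed Chinese-English text
#'
#' Splits a string into tokens suited to code-mixing analysis:
#' \itemize{
#'   \item every CJK (Han) character is its own token, tagged `HAN`;
#'   \item maximal runs of Latin letters (optionally with internal
#'     apostrophes or hyphens) form one token, tagged `LATIN`;
#'   \item maximal digit runs and individual punctuation/symbol characters
#'     are tagged `NEUTRAL` (language-independent, the \emph{u} tokens of
#'     the code-mixing index);
#'   \item whitespace never appears inside a token.
#' }
#' Chinese is deliberately segmented per character (no word segmentation)
#' so that CMI token counts and vocabulary checks are reproducible without
#' an external segmenter.  Romanized abbreviations such as the ROC-calendar
#' prefix "mk" are Latin tokens, not neutral ones: only digits, punctuation
#' and symbols count as language-independent.
#'
#' Offsets are 0-based, half-open character (not byte) offsets.
#'
#' @param text A single string (NA or "" give an empty token table).
#' @return A data.frame with columns `text`, `start`, `end`, `lang`
#'   (one of "LATIN", "HAN", "NEUTRAL").
#' @examples
#' tokenize_mixed("Dr. 張家明")  # Dr / . / 3 Han chars
#' tokenize_mixed("2141/03/09")              # all NEUTRAL
#' @export
tokenize_mixed <- function(text) {
  empty <- data.frame(text = character(), start = integer(), end = integer(),
                      lang = character(), stringsAsFactors = FALSE)
  if (length(text) != 1L) stop("tokenize_mixed() expects a single string")
  if (is.na(text) || !nzchar(text)) return(empty)
  pat <- "[\\p{Latin}]+(?:['-][\\p{Latin}]+)*|\\p{Han}|[0-9]+|\\S"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  toks <- substring(text, starts, starts + lens - 1L)
  lang <- ifelse(grepl("\\p{Han}", toks, perl = TRUE), "HAN",
          ifelse(grepl("\\p{Latin}", toks, perl = TRUE), "LATIN", "NEUTRAL"))
  data.frame(text = toks, start = starts - 1L, end = starts + lens - 1L,
             lang = lang, stringsAsFactors = FALSE)
}

# 0-based half-open substring helper
substr0 <- function(x, start, end) substring(x, start + 1L, end)

#' Construct a sentence object
#'
#' A sentence couples raw text with its token table and a code-mixing
#' category.  The category is derived from the token language tags unless
#' supplied.
#'
#' @param id Sentence identifier.
#' @param text Sentence text.
#' @param category Optional category; computed by [categorize_sentence()]
#'   when `NULL`.
#' @param start,end Optional document-level 0-based half-open offsets.
#' @return An object of class `cm_sentence`.
#' @export
cm_sentence <- function(id, text, category = NULL, start = NA_integer_,
                        end = NA_integer_) {
  tokens <- tokenize_mixed(text)
  if (is.null(category)) category <- categorize_tokens(tokens)
  structure(
    list(id = id, text = text, tokens = tokens, category = category,
         start = as.integer(start), end = as.integer(end)),
    class = "cm_sentence"
  )
}

#' @export
print.cm_sentence <- function(x, ...) {
  cat("<cm_sentence ", x$id, "> [", x$category, "] ",
      substr(x$text, 1, 60), "\n", sep = "")
  invisible(x)
}

sentence_categories <- function() {
  c("ENGLISH_ONLY", "CHINESE_ONLY", "MIXED", "NUMERIC_SYMBOLIC")
}
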