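#' Per-sentence code-mixing index (CMI)
#'
#' For a tokenized sentence with `n` tokens, `u` of which are
#' language-independent (digits, punctuation, symbols), and `W` the token
#' count of the most frequent language, the code-mixing index is
#' \deqn{CMI = 1 - W / (n - u).}
#' The index is 0 when the sentence is monolingual or consists solely of
#' numeric/symbolic tokens, and is bounded by 0.5 for two languages.
#'
#' @param x A `cm_sentence` or a token data.frame from [tokenize_mixed()].
#' @return An object of class `cmi_result`: list with `value` (fraction in
#'   \[0, 0.5\]), `n`, `u`, `counts` (named: EN, ZH), `W` and `dominant`
#'   ("EN", "ZH" or "NONE").
#' @examples
#' compute_cmi(cm_sentence("s1", "follow-up in Dr. 張家明 OPD"))
#' @export
compute_cmi <- function(x) {
  tokens <- if (inherits(x, "cm_sentence")) x$tokens else x
  n  <- nrow(tokens)
  en <- sum(tokens$lang == "LATIN")
  zh <- sum(tokens$lang == "HAN")
  u  <- sum(tokens$lang == "NEUTRAL")
  dominant <- if (en == 0L && zh == 0L) "NONE" else if (zh > en) "ZH" else "EN"
  W <- max(en, zh)
  value <- if (n == 0L || n == u || en == 0L || zh == 0L) 0 else 1 - W / (n - u)
  structure(
    list(value = value, n = n, u = u, counts = c(EN = en, ZH = zh),
         W = W, dominant = dominant),
    class = "cmi_result"
  )
}

#' @export
print.cmi_result <- function(x, ...) {
  cat(sprintf("<cmi_result> value=%.4f n=%d u=%d EN=%d ZH=%d dominant=%s\n",
              x$value, x$n, x$u, x$counts[["EN"]], x$counts[["ZH"]],
              x$dominant))
  invisible(x)
}

#' Dominant language of a sentence
#'
#' The language with the strictly greater token count; ties are resolved to
#' English (the corpora this package emulates are majority-English; the
#' tie-break is configurable).  "NONE" when the sentence has neither Latin
#' nor Han tokens.
#'
#' @param x A `cm_sentence` or token data.frame.
#' @param tie One of "EN", "ZH": winner on exact ties.
#' @return "EN", "ZH" or "NONE".
#' @export
dominant_language <- function(x, tie = c("EN", "ZH")) {
  tie <- match.arg(tie)
  tokens <- if (inherits(x, "cm_sentence")) x$tokens else x
  en <- sum(tokens$lang == "LATIN")
  zh <- sum(tokens$lang == "HAN")
  if (en == 0L && zh == 0L) return("NONE")
  if (en == zh) return(tie)
  if (en > zh) "EN" else "ZH"
}

categorize_tokens <- function(tokens) {
  has_en <- any(tokens$lang == "LATIN")
  has_zh <- any(tokens$lang == "HAN")
  if (!has_en && !has_zh) "NUMERIC_SYMBOLIC"
  else if (has_en && !has_zh) "ENGLISH_ONLY"
  else if (!has_en && has_zh) "CHINESE_ONLY"
  else "MIXED"
}

#' Categorize a sentence by its code-mixing characteristics
#'
#' Sentences fall into 4 groups: `ENGLISH_ONLY` (Latin tokens, no Han),
#' `CHINESE_ONLY` (Han, no Latin), `MIXED` (both), and `NUMERIC_SYMBOLIC`
#' (only language-independent tokens; empty sentences also land here).
#'
#' @param x A `cm_sentence`, a token data.frame, or a raw string.
#' @return One of the four category labels.
#' @export
categorize_sentence <- function(x) {
  tokens <- if (inherits(x, "cm_sentence")) x$tokens
            else if (is.character(x)) tokenize_mixed(x)
            else x
  categorize_tokens(tokens)
}

corpus_sentences <- function(corpus) {
  unlist(lapply(corpus, function(d) d$sentences), recursive = FALSE)
}

#' Average CMI over sentences dominated by one language
#'
#' The mean per-sentence CMI over the set of L-dominated sentences in a
#' corpus (zero-CMI members included), reported on a x100 scale.
#'
#' @param corpus A `cm_corpus` (list of documents).
#' @param language "EN" or "ZH".
#' @param scale100 Report on the x100 scale (default) or as a fraction.
#' @return A number; 0 when no sentence is dominated by `language`.
#' @export
avg_cmi <- function(corpus, language = c("EN", "ZH"), scale100 = TRUE) {
  language <- match.arg(language)
  sents <- corpus_sentences(corpus)
  res <- lapply(sents, compute_cmi)
  dom <- vapply(res, function(r) r$dominant, character(1))
  vals <- vapply(res, function(r) r$value, numeric(1))
  keep <- dom == language
  m <- if (!any(keep)) 0 else mean(vals[keep])
  if (scale100) 100 * m else m
}

#' Corpus-level code-mixing index (CMIC)
#'
#' The sentence-count-weighted mean of per-sentence CMI over all
#' language-dominated sentences (dominant != "NONE"), reported x100.  This
#' makes CMIC the convex combination of the English- and Chinese-dominated
#' averages weighted by the sizes of the two dominated sets.
#'
#' @inheritParams avg_cmi
#' @return A number in \[0, 50\] on the x100 scale.
#' @export
cmic <- function(corpus, scale100 = TRUE) {
  sents <- corpus_sentences(corpus)
  res <- lapply(sents, compute_cmi)
  dom <- vapply(res, function(r) r$dominant, character(1))
  vals <- vapply(res, function(r) r$value, numeric(1))
  keep <- dom != "NONE"
  m <- if (!any(keep)) 0 else mean(vals[keep])
  if (scale100) 100 * m else m
}

default_cmi_edges <- function() c(0, 0.1, 0.2, 0.3, 0.4, 0.5)

#' Bin sentences by CMI level
#'
#' Partitions CMI values into a zero bin plus half-open intervals.  The
#' default is the 6-bin scheme \{0\}, (0,0.1\], ..., (0.4,0.5\].
#'
#' @param values Numeric CMI values (fractions in \[0, 0.5\]).
#' @param edges Strictly increasing interior/right edges spanning (0, 0.5\];
#'   the zero bin is always present.
#' @return A character vector of bin labels, a factor-like partition.
#' @export
bin_by_cmi <- function(values, edges = default_cmi_edges()) {
  stopifnot(all(diff(edges) > 0))
  if (any(values < 0 | values > 0.5 + 1e-12)) {
    stop("CMI values must lie in [0, 0.5]")
  }
  edges <- unique(c(0, edges))
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  int_labs <- sprintf("(%g,%g]", lo, hi)
  out <- character(length(values))
  zero <- values == 0
  out[zero] <- "0"
  if (any(!zero)) {
    # value v falls in (lo[i], hi[i]] where i is the first hi >= v
    idx <- vapply(values[!zero], function(v) which(hi >= v - 1e-12)[1],
                  integer(1))
    out[!zero] <- int_labs[idx]
  }
  out
}

#' CMI profile of a corpus
#'
#' Computes the corpus-level code-mixing summary: AvgCMI for English- and
#' Chinese-dominated sentences, CMIC, sentence-category counts, and a
#' histogram of sentences per CMI bin.
#'
#' @inheritParams avg_cmi
#' @param edges CMI bin edges, see [bin_by_cmi()].
#' @return A list of class `cmi_profile` with elements `avg_cmi_en`,
#'   `avg_cmi_zh`, `cmic` (all x100), `category_counts`, `histogram` and
#'   `per_sentence` (data.frame of id, category, cmi, dominant, bin).
#' @export
cmi_profile <- function(corpus, edges = default_cmi_edges()) {
  sents <- corpus_sentences(corpus)
  res <- lapply(sents, compute_cmi)
  df <- data.frame(
    id = vapply(sents, function(s) s$id, character(1)),
    category = vapply(sents, function(s) s$category, character(1)),
    cmi = vapply(res, function(r) r$value, numeric(1)),
    dominant = vapply(res, function(r) r$dominant, character(1)),
    stringsAsFactors = FALSE
  )
  df$bin <- if (nrow(df)) bin_by_cmi(df$cmi, edges) else character(0)
  dom_vals <- function(l) df$cmi[df$dominant == l]
  mean0 <- function(v) if (length(v)) mean(v) else 0
  structure(
    list(
      avg_cmi_en = 100 * mean0(dom_vals("EN")),
      avg_cmi_zh = 100 * mean0(dom_vals("ZH")),
      cmic = 100 * mean0(df$cmi[df$dominant != "NONE"]),
      category_counts = table(factor(df$category,
                                     levels = sentence_categories())),
      histogram = table(df$bin),
      per_sentence = df
    ),
    class = "cmi_profile"
  )
}

#' @export
print.cmi_profile <- function(x, ...) {
  cat(sprintf("<cmi_profile> AvgCMI_EN=%.2f AvgCMI_ZH=%.2f CMIC=%.2f (x100)\n",
              x$avg_cmi_en, x$avg_cmi_zh, x$cmic))
  print(x$category_counts)
  invisible(x)
}
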