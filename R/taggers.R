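#' @name taggers
#' @title De-identification taggers
#' @description
#' The dictionary-based approach (DBA) is the classic baseline: compile a
#' dictionary of every token observed in the training set and assign each
#' token its most frequent gold BILOU tag; unseen tokens are tagged O.
#' Per-token lookup ignores the BILOU grammar, so predictions pass through
#' [repair_bilou()] before span decoding.  A generic tagger-backend
#' contract ([new_tagger()]) allows plugging in learned sequence taggers
#' behind the same interface.
NULL

#' Build the most-frequent-tag dictionary from a training corpus
#'
#' Counts, for every token text in the TRAIN split, how often it carries
#' each BILOU label (O included), and stores the argmax.  Ties are broken
#' by lexicographic order of the label strings and flagged.  Keys are raw
#' token texts and case-sensitive by default: PHI like "NKUST" is
#' case-bearing.
#'
#' @param corpus A `cm_corpus` with gold annotations.
#' @param case_fold Lower-case Latin keys (off by default).
#' @return An object of class `tag_dictionary`: list with `entries`
#'   (named character: token -> label), `ties` (tokens whose argmax was
#'   tied), `counts` (named list of label count tables) and `case_fold`.
#' @export
build_dictionary <- function(corpus, case_fold = FALSE) {
  toks <- character(0)
  labs <- character(0)
  for (doc in corpus) {
    if (doc$split != "TRAIN") next
    for (s in doc$sentences) {
      tags <- encode_bilou(s$tokens, sentence_annotations(doc, s))
      toks <- c(toks, s$tokens$text)
      labs <- c(labs, tags)
    }
  }
  if (case_fold) toks <- tolower(toks)
  if (!length(toks)) {
    return(structure(list(entries = character(0), ties = character(0),
                          counts = list(), case_fold = case_fold),
                     class = "tag_dictionary"))
  }
  tab <- table(toks, labs)
  best <- apply(tab, 1, function(r) {
    m <- max(r)
    winners <- sort(names(r)[r == m])
    winners[1]
  })
  tied <- apply(tab, 1, function(r) sum(r == max(r)) > 1)
  structure(
    list(entries = best, ties = names(best)[tied],
         counts = tab, case_fold = case_fold),
    class = "tag_dictionary"
  )
}

#' @export
print.tag_dictionary <- function(x, ...) {
  cat("<tag_dictionary> ", length(x$entries), " token types (",
      length(x$ties), " ties", if (x$case_fold) ", case-folded", ")\n",
      sep = "")
  invisible(x)
}

#' Predict BILOU tags for a sentence by dictionary lookup
#'
#' @param dict A `tag_dictionary`.
#' @param sentence A `cm_sentence`.
#' @param repair Pass the raw lookup through [repair_bilou()] (default).
#' @return Character label vector aligned with the sentence tokens.
#' @export
dba_predict <- function(dict, sentence, repair = TRUE) {
  keys <- sentence$tokens$text
  if (dict$case_fold) keys <- tolower(keys)
  labels <- unname(dict$entries[keys])
  labels[is.na(labels)] <- "O"
  if (repair) labels <- repair_bilou(labels)
  labels
}

#' Tagger backend contract
#'
#' A tagger is a list with functions `fit(tagger, corpus)` returning a
#' fitted tagger and `predict(tagger, sentence)` returning one BILOU label
#' per token, plus a `deterministic` flag and optional `seed`.
#'
#' @param fit Function(tagger, corpus) -> fitted tagger.
#' @param predict Function(tagger, sentence) -> label vector.
#' @param deterministic Logical flag declared by the backend.
#' @param seed Optional seed consumed by stochastic backends.
#' @param name Display name.
#' @return An object of class `cm_tagger`.
#' @export
new_tagger <- function(fit, predict, deterministic = TRUE, seed = NULL,
                       name = "tagger") {
  structure(list(fit = fit, predict = predict,
                 deterministic = deterministic, seed = seed, name = name),
            class = "cm_tagger")
}

#' @export
print.cm_tagger <- function(x, ...) {
  cat("<cm_tagger ", x$name, "> deterministic=", x$deterministic, "\n",
      sep = "")
  invisible(x)
}

#' The dictionary-based baseline as a tagger backend
#'
#' @param case_fold See [build_dictionary()].
#' @return A `cm_tagger`.
#' @export
dba_tagger <- function(case_fold = FALSE) {
  new_tagger(
    fit = function(tagger, corpus) {
      tagger$model <- build_dictionary(corpus, case_fold = case_fold)
      tagger
    },
    predict = function(tagger, sentence) {
      if (is.null(tagger$model)) stop("tagger has not been fitted")
      dba_predict(tagger$model, sentence)
    },
    deterministic = TRUE,
    name = "dba"
  )
}

#' Fit a tagger on a corpus
#' @param tagger A `cm_tagger`.
#' @param corpus Training `cm_corpus`.
#' @return The fitted tagger.
#' @export
fit_tagger <- function(tagger, corpus) tagger$fit(tagger, corpus)

#' Predict annotations for every TEST document of a corpus
#'
#' Runs the tagger sentence by sentence, repairs the label sequences and
#' decodes them into document-level annotations.
#'
#' @param tagger A fitted `cm_tagger`.
#' @param corpus A `cm_corpus`.
#' @param split Which split to predict on (default "TEST").
#' @return A `cm_corpus` of the selected documents carrying predicted
#'   annotations in place of gold ones.
#' @export
predict_corpus <- function(tagger, corpus, split = "TEST") {
  docs <- lapply(unclass(corpus), function(doc) {
    if (doc$split != split) return(NULL)
    anns <- list()
    for (s in doc$sentences) {
      labels <- repair_bilou(tagger$predict(tagger, s))
      spans <- decode_bilou(s$tokens, labels)
      if (nrow(spans)) {
        spans$start <- spans$start + s$start
        spans$end <- spans$end + s$start
        anns[[length(anns) + 1L]] <- spans
      }
    }
    ann <- if (length(anns)) do.call(rbind, anns) else NULL
    with_annotations(doc, ann)
  })
  cm_corpus(Filter(Negate(is.null), docs))
}
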