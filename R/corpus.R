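#' @name corpus
#' @title Documents, annotations and corpora
#' @description
#' A document couples raw text with a sentence segmentation and a table of
#' PHI annotations.  All offsets are 0-based, half-open, character offsets
#' into the document text; every annotation lies inside exactly one
#' sentence and its `mention` equals the document substring it covers.
NULL

empty_annotations <- function() {
  data.frame(doc_id = character(), start = integer(), end = integer(),
             fine_type = character(), mention = character(),
             stringsAsFactors = FALSE)
}

#' Construct a document
#'
#' @param id Document identifier.
#' @param sentences List of `cm_sentence` objects with document-level
#'   `start`/`end` offsets; their texts must concatenate to the document
#'   text.
#' @param annotations data.frame with columns `start`, `end`, `fine_type`
#'   (document-level offsets); `doc_id` and `mention` are filled in.
#' @param split "TRAIN" or "TEST".
#' @return An object of class `cm_document`.
#' @export
cm_document <- function(id, sentences, annotations = NULL,
                        split = c("TRAIN", "TEST")) {
  split <- match.arg(split)
  text <- paste(vapply(sentences, function(s) s$text, character(1)),
                collapse = "")
  if (is.null(annotations) || nrow(annotations) == 0) {
    annotations <- empty_annotations()
  } else {
    annotations <- annotations[order(annotations$start), , drop = FALSE]
    annotations$doc_id <- id
    annotations$mention <- substr0(text, annotations$start, annotations$end)
    rownames(annotations) <- NULL
    annotations <- annotations[, c("doc_id", "start", "end", "fine_type",
                                   "mention")]
    if (nrow(annotations) > 1 &&
        any(annotations$start[-1] < annotations$end[-nrow(annotations)])) {
      stop("annotations overlap in document ", id)
    }
  }
  structure(
    list(id = id, text = text, sentences = sentences,
         annotations = annotations, split = split),
    class = "cm_document"
  )
}

#' @export
print.cm_document <- function(x, ...) {
  cat("<cm_document ", x$id, "> [", x$split, "] ",
      length(x$sentences), " sentences, ", nrow(x$annotations),
      " annotations\n", sep = "")
  invisible(x)
}

#' Construct a corpus (list of documents)
#'
#' @param docs List of `cm_document` objects.
#' @return An object of class `cm_corpus`.
#' @export
cm_corpus <- function(docs) {
  ids <- vapply(docs, function(d) d$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate document ids")
  structure(docs, class = "cm_corpus", names = unname(ids))
}

#' @export
print.cm_corpus <- function(x, ...) {
  splits <- vapply(x, function(d) d$split, character(1))
  cat("<cm_corpus> ", length(x), " documents (",
      sum(splits == "TRAIN"), " train / ", sum(splits == "TEST"),
      " test), ", sum(vapply(x, function(d) length(d$sentences), integer(1))),
      " sentences\n", sep = "")
  invisible(x)
}

#' Subset a corpus by split
#' @param corpus A `cm_corpus`.
#' @param split "TRAIN" or "TEST".
#' @return A `cm_corpus` with the matching documents.
#' @export
corpus_split <- function(corpus, split = c("TRAIN", "TEST")) {
  split <- match.arg(split)
  cm_corpus(unclass(corpus)[vapply(corpus, function(d) d$split == split,
                                   logical(1))])
}

#' Annotations of a document restricted to one sentence
#'
#' Returns the document's annotations that lie inside the given sentence,
#' with offsets translated to sentence-relative coordinates.
#'
#' @param doc A `cm_document`.
#' @param sentence One of its `cm_sentence` elements.
#' @return data.frame with `start`, `end`, `fine_type`, `mention`
#'   (sentence-relative 0-based offsets).
#' @export
sentence_annotations <- function(doc, sentence) {
  ann <- doc$annotations
  keep <- ann$start >= sentence$start & ann$end <= sentence$end
  out <- ann[keep, c("start", "end", "fine_type", "mention"), drop = FALSE]
  out$start <- out$start - sentence$start
  out$end <- out$end - sentence$start
  rownames(out) <- NULL
  out
}

#' Gold BILOU labels for every sentence of a corpus
#'
#' @param corpus A `cm_corpus`.
#' @return A list (one element per document) of lists (one per sentence) of
#'   label vectors.
#' @export
corpus_gold_tags <- function(corpus) {
  lapply(corpus, function(doc) {
    lapply(doc$sentences, function(s) {
      encode_bilou(s$tokens, sentence_annotations(doc, s))
    })
  })
}

#' Vocabulary of token texts in a corpus split
#'
#' @param corpus A `cm_corpus`.
#' @param split Which split to harvest (default "TRAIN").
#' @return Character vector of unique token texts.
#' @export
corpus_vocabulary <- function(corpus, split = "TRAIN") {
  docs <- unclass(corpus)[vapply(corpus, function(d) d$split == split,
                                 logical(1))]
  unique(unlist(lapply(docs, function(d) {
    unlist(lapply(d$sentences, function(s) s$tokens$text))
  })))
}

# Rebuild a document with a new set of annotations (same text/sentences).
with_annotations <- function(doc, annotations) {
  cm_document(doc$id, doc$sentences, annotations, doc$split)
}
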