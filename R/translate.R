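#' @name translate_route
#' @title CMI-driven monolingual normalization
#' @description
#' Code-mixed sentences can be normalized into their dominant language
#' before training/prediction: a sentence with CMI = 0 passes through
#' unchanged; otherwise it is routed to English or Chinese translation
#' according to its dominant language.  Gold annotations survive
#' translation by mask-and-restore: PHI mentions are replaced by opaque
#' placeholders before the translator sees the text and restored (with
#' recomputed offsets) afterwards.  The machine-translation model itself
#' is out of scope: translators are a contract, and the package bundles
#' identity and mock implementations.
NULL

#' Translator contract and bundled implementations
#'
#' A translator is a list with `translate(text, target)` ("EN" or "ZH")
#' returning a string, plus a `deterministic` flag.
#' `identity_translator()` returns its input unchanged;
#' `mock_translator(fn)` wraps an arbitrary string function (applied to
#' the masked text), useful in tests.
#'
#' @param fn Function(text, target) -> text.
#' @param deterministic Declared determinism flag.
#' @return An object of class `cm_translator`.
#' @export
new_translator <- function(fn, deterministic = TRUE) {
  structure(list(translate = fn, deterministic = deterministic),
            class = "cm_translator")
}

#' @rdname new_translator
#' @export
identity_translator <- function() {
  new_translator(function(text, target) text)
}

#' @rdname new_translator
#' @export
mock_translator <- function(fn) {
  new_translator(function(text, target) fn(text, target))
}

#' Route a sentence through the normalization decision
#'
#' @param sentence A `cm_sentence`.
#' @return list(action, reason): `PASS`/`zero_cmi` when CMI = 0, else
#'   `TO_EN`/`en_dominant` or `TO_ZH`/`zh_dominant`.
#' @export
route <- function(sentence) {
  r <- compute_cmi(sentence)
  if (r$value == 0) return(list(action = "PASS", reason = "zero_cmi"))
  stopifnot(r$dominant != "NONE")  # impossible when CMI > 0
  if (r$dominant == "EN") list(action = "TO_EN", reason = "en_dominant")
  else list(action = "TO_ZH", reason = "zh_dominant")
}

mask_token <- function(i) sprintf("<PHI%d>", i)

#' Normalize a corpus into dominant-language monolingual text
#'
#' Every routed sentence is rewritten by the translator; sentences with
#' CMI = 0 are never sent to the translator.  PHI mentions are masked with
#' placeholders `<PHI1>`, `<PHI2>`, ... before translation and restored
#' afterwards, so annotation count and fine types are invariant.  If the
#' translator drops or duplicates a placeholder the sentence is kept
#' untranslated (fail-safe) and counted in attribute `"failed_sentences"`.
#' With the identity translator, normalization is the identity on both
#' texts and annotations.
#'
#' @param corpus A `cm_corpus`.
#' @param translator A `cm_translator`.
#' @return A normalized `cm_corpus`; attribute `"translator_calls"` counts
#'   actual translate() invocations.
#' @export
normalize_corpus <- function(corpus, translator) {
  stopifnot(inherits(translator, "cm_translator"))
  calls <- 0L
  failed <- 0L
  docs <- lapply(unclass(corpus), function(doc) {
    off <- 0L
    new_sents <- vector("list", length(doc$sentences))
    new_anns <- vector("list", length(doc$sentences))
    for (j in seq_along(doc$sentences)) {
      s <- doc$sentences[[j]]
      ann <- sentence_annotations(doc, s)
      dec <- route(s)
      if (dec$action == "PASS") {
        txt <- s$text
        rows <- ann
      } else {
        target <- if (dec$action == "TO_EN") "EN" else "ZH"
        # mask mentions
        masked <- s$text
        if (nrow(ann)) {
          pieces <- character(0)
          cursor <- 0L
          for (i in seq_len(nrow(ann))) {
            pieces <- c(pieces, substr0(s$text, cursor, ann$start[i]),
                        mask_token(i))
            cursor <- ann$end[i]
          }
          pieces <- c(pieces, substr0(s$text, cursor, nchar(s$text)))
          masked <- paste(pieces, collapse = "")
        }
        has_nl <- endsWith(masked, "\n")
        body <- if (has_nl) substr(masked, 1, nchar(masked) - 1L) else masked
        translated <- translator$translate(body, target)
        calls <<- calls + 1L
        if (has_nl) translated <- paste0(translated, "\n")
        # restore mentions
        ok <- TRUE
        rows <- ann
        txt <- translated
        if (nrow(ann)) {
          for (i in seq_len(nrow(ann))) {
            hit <- gregexpr(mask_token(i), txt, fixed = TRUE)[[1]]
            if (hit[1] == -1L || length(hit) != 1L) { ok <- FALSE; break }
            pos0 <- hit[1] - 1L
            txt <- paste0(substr0(txt, 0, pos0), ann$mention[i],
                          substr0(txt, pos0 + nchar(mask_token(i)),
                                  nchar(txt)))
            rows$start[i] <- pos0
            rows$end[i] <- pos0 + nchar(ann$mention[i])
          }
        }
        if (!ok) {
          failed <<- failed + 1L
          txt <- s$text
          rows <- ann
        }
      }
      if (nrow(rows)) {
        rows$start <- rows$start + off
        rows$end <- rows$end + off
        new_anns[[j]] <- rows[, c("start", "end", "fine_type")]
      }
      new_sents[[j]] <- cm_sentence(s$id, txt, start = off,
                                    end = off + nchar(txt))
      off <- off + nchar(txt)
    }
    ann <- if (any(!vapply(new_anns, is.null, logical(1)))) {
      do.call(rbind, new_anns)
    } else NULL
    cm_document(doc$id, new_sents, ann, doc$split)
  })
  out <- cm_corpus(docs)
  attr(out, "translator_calls") <- calls
  attr(out, "failed_sentences") <- failed
  out
}
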