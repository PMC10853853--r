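#' Read and write annotated corpora
#'
#' Three dialects are supported:
#' \describe{
#'   \item{json}{One UTF-8 JSON file holding a list of document objects
#'     `{id, text, split, sentences: [{id, start, end, category}],
#'     annotations: [{start, end, fine_type}]}`.  This is the lossless
#'     native format: a write/read round trip preserves documents exactly.}
#'   \item{conll}{One token per line as `token<TAB>BILOU-label`, a blank
#'     line between sentences and a `-DOCSTART- <id> <split>` header per
#'     document.  Whitespace between tokens is not recorded, so reading
#'     reconstructs sentence text by joining tokens with single spaces
#'     (Han characters are joined without spaces); tags and spans relative
#'     to that text are preserved.}
#'   \item{standoff}{brat-style `.txt`/`.ann` pairs under `train/` and
#'     `test/` subdirectories of `path`, with one
#'     `T<n><TAB>type start end<TAB>mention` line per annotation.}
#' }
#'
#' @param corpus A `cm_corpus`.
#' @param path File (json, conll) or directory (standoff) path.
#' @param format One of "json", "conll", "standoff".
#' @return `read_corpus()` returns a `cm_corpus`; `write_corpus()` returns
#'   `path` invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("json", "conll",
                                                  "standoff")) {
  format <- match.arg(format)
  switch(format,
         json = write_corpus_json(corpus, path),
         conll = write_corpus_conll(corpus, path),
         standoff = write_corpus_standoff(corpus, path))
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path, format = c("json", "conll", "standoff")) {
  format <- match.arg(format)
  switch(format,
         json = read_corpus_json(path),
         conll = read_corpus_conll(path),
         standoff = read_corpus_standoff(path))
}

write_corpus_json <- function(corpus, path) {
  docs <- lapply(corpus, function(d) {
    list(
      id = d$id,
      text = d$text,
      split = d$split,
      sentences = lapply(d$sentences, function(s) {
        list(id = s$id, start = s$start, end = s$end, category = s$category)
      }),
      annotations = if (nrow(d$annotations)) {
        lapply(seq_len(nrow(d$annotations)), function(i) {
          list(start = d$annotations$start[i], end = d$annotations$end[i],
               fine_type = d$annotations$fine_type[i])
        })
      } else list()
    )
  })
  jsonlite::write_json(unname(docs), path, auto_unbox = TRUE, digits = NA)
}

read_corpus_json <- function(path) {
  raw <- jsonlite::read_json(path)
  docs <- lapply(raw, function(d) {
    for (f in c("id", "text", "split", "sentences")) {
      if (is.null(d[[f]])) {
        stop("malformed JSON corpus document (id=",
             if (is.null(d$id)) "?" else d$id, "): missing field '", f, "'")
      }
    }
    sentences <- lapply(d$sentences, function(s) {
      txt <- substr0(d$text, s$start, s$end)
      cm_sentence(s$id, txt, category = s$category,
                  start = s$start, end = s$end)
    })
    ann <- if (length(d$annotations)) {
      data.frame(
        start = vapply(d$annotations, function(a) as.integer(a$start),
                       integer(1)),
        end = vapply(d$annotations, function(a) as.integer(a$end),
                     integer(1)),
        fine_type = vapply(d$annotations, function(a) a$fine_type,
                           character(1)),
        stringsAsFactors = FALSE
      )
    } else NULL
    cm_document(d$id, sentences, ann, d$split)
  })
  cm_corpus(docs)
}

write_corpus_conll <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (d in corpus) {
    writeLines(paste("-DOCSTART-", d$id, d$split), con)
    for (s in d$sentences) {
      labels <- encode_bilou(s$tokens, sentence_annotations(d, s))
      if (nrow(s$tokens)) {
        writeLines(paste(s$tokens$text, labels, sep = "\t"), con)
      }
      writeLines("", con)
    }
  }
}

# Rebuild sentence text from tokens: single space between tokens except
# that Han characters attach directly to a preceding Han character.
join_tokens <- function(toks) {
  if (!length(toks)) return("")
  han <- grepl("\\p{Han}", toks, perl = TRUE)
  sep <- ifelse(han[-length(han)] & han[-1], "", " ")
  paste0(toks[1], paste0(sep, toks[-1], collapse = ""))
}

read_corpus_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  docs <- list()
  cur_id <- NULL; cur_split <- "TRAIN"
  cur_sents <- list(); cur_tokens <- character(); cur_labels <- character()
  sent_i <- 0L
  flush_sentence <- function() {
    if (!length(cur_tokens)) return()
    sent_i <<- sent_i + 1L
    txt <- join_tokens(cur_tokens)
    s <- cm_sentence(paste0(cur_id, "-s", sent_i), txt)
    if (nrow(s$tokens) != length(cur_tokens)) {
      stop("CoNLL document ", cur_id, ": tokens do not round-trip near '",
           txt, "'")
    }
    attr(s, "labels") <- cur_labels
    cur_sents[[length(cur_sents) + 1L]] <<- s
    cur_tokens <<- character(); cur_labels <<- character()
  }
  flush_doc <- function() {
    flush_sentence()
    if (is.null(cur_id)) return()
    # assign document-level offsets and decode labels into annotations
    off <- 0L
    anns <- list()
    sents <- lapply(cur_sents, function(s) {
      s$start <- off
      s$end <- off + nchar(s$text)
      spans <- decode_bilou(s$tokens, attr(s, "labels"))
      if (nrow(spans)) {
        spans$start <- spans$start + off
        spans$end <- spans$end + off
        anns[[length(anns) + 1L]] <<- spans
      }
      off <<- off + nchar(s$text) + 1L  # sentences joined by "\n"
      attr(s, "labels") <- NULL
      s
    })
    # rebuild texts joined with newline: append "\n" to all but last
    n <- length(sents)
    sents <- lapply(seq_len(n), function(i) {
      s <- sents[[i]]
      if (i < n) {
        cm_sentence(s$id, paste0(s$text, "\n"), category = s$category,
                    start = s$start, end = s$end + 1L)
      } else s
    })
    ann <- if (length(anns)) do.call(rbind, anns) else NULL
    docs[[length(docs) + 1L]] <<- cm_document(cur_id, sents, ann, cur_split)
    cur_sents <<- list(); sent_i <<- 0L
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (startsWith(line, "-DOCSTART-")) {
      flush_doc()
      parts <- strsplit(line, " ", fixed = TRUE)[[1]]
      if (length(parts) < 2) stop("malformed -DOCSTART- at line ", ln)
      cur_id <- parts[2]
      cur_split <- if (length(parts) >= 3) parts[3] else "TRAIN"
    } else if (!nzchar(line)) {
      flush_sentence()
    } else {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2) {
        stop("malformed CoNLL line ", ln, " in document ",
             if (is.null(cur_id)) "?" else cur_id, ": '", line, "'")
      }
      cur_tokens <- c(cur_tokens, parts[1])
      cur_labels <- c(cur_labels, parts[2])
    }
  }
  flush_doc()
  cm_corpus(docs)
}

write_corpus_standoff <- function(corpus, path) {
  for (sub in c("train", "test")) {
    dir.create(file.path(path, sub), recursive = TRUE, showWarnings = FALSE)
  }
  for (d in corpus) {
    sub <- if (d$split == "TRAIN") "train" else "test"
    base <- file.path(path, sub, d$id)
    writeLines(d$text, paste0(base, ".txt"), useBytes = FALSE)
    ann <- d$annotations
    lines <- if (nrow(ann)) {
      sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(ann)), ann$fine_type,
              ann$start, ann$end, ann$mention)
    } else character(0)
    con <- file(paste0(base, ".ann"), open = "w", encoding = "UTF-8")
    writeLines(lines, con)
    close(con)
  }
  invisible(path)
}

read_corpus_standoff <- function(path) {
  docs <- list()
  for (sub in c("train", "test")) {
    split <- if (sub == "train") "TRAIN" else "TEST"
    dirp <- file.path(path, sub)
    if (!dir.exists(dirp)) next
    txts <- sort(list.files(dirp, pattern = "\\.txt$", full.names = TRUE))
    for (tf in txts) {
      id <- sub("\\.txt$", "", basename(tf))
      text <- paste(readLines(tf, encoding = "UTF-8"), collapse = "\n")
      af <- sub("\\.txt$", ".ann", tf)
      ann <- NULL
      if (file.exists(af)) {
        alines <- readLines(af, encoding = "UTF-8")
        alines <- alines[nzchar(alines)]
        if (length(alines)) {
          rows <- lapply(seq_along(alines), function(i) {
            parts <- strsplit(alines[i], "\t", fixed = TRUE)[[1]]
            if (length(parts) < 2 || !grepl("^T", parts[1])) {
              stop("malformed standoff line ", i, " in ", basename(af))
            }
            mid <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
            k <- length(mid)
            data.frame(
              fine_type = paste(mid[seq_len(k - 2)], collapse = " "),
              start = as.integer(mid[k - 1]),
              end = as.integer(mid[k]),
              stringsAsFactors = FALSE
            )
          })
          ann <- do.call(rbind, rows)
        }
      }
      # resegment by newline, preserving exact offsets
      sents <- split_text_sentences(id, text)
      docs[[length(docs) + 1L]] <- cm_document(id, sents, ann, split)
    }
  }
  cm_corpus(docs)
}

# Split document text at newlines into sentences covering the text exactly
# (each sentence keeps its trailing newline; the spans partition the text).
split_text_sentences <- function(id, text) {
  if (!nchar(text)) return(list(cm_sentence(paste0(id, "-s1"), "",
                                            start = 0L, end = 0L)))
  pieces <- strsplit(text, "(?<=\n)", perl = TRUE)[[1]]
  off <- 0L
  lapply(seq_along(pieces), function(i) {
    s <- cm_sentence(paste0(id, "-s", i), pieces[i],
                     start = off, end = off + nchar(pieces[i]))
    off <<- off + nchar(pieces[i])
    s
  })
}
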