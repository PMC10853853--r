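# Shared fixture builders.  Everything is generated in code; no files.

# deterministic token table: k tokens with given languages, 1-char texts
mk_tokens <- function(langs) {
  txt <- vapply(seq_along(langs), function(i) {
    switch(langs[i],
           LATIN = letters[(i %% 26) + 1],
           HAN = intToUtf8(0x4E00 + i),
           NEUTRAL = as.character(i %% 10))
  }, character(1))
  n <- nchar(txt)
  end <- cumsum(n + 1L)
  data.frame(text = txt, start = end - n - 1L, end = end - 1L,
             lang = langs, stringsAsFactors = FALSE)
}

# random valid (tokens, spans) pair for codec round-trip properties
rand_tokens_spans <- function(n_tokens = 12, types = phi_schema()$fine_types) {
  langs <- sample(c("LATIN", "HAN", "NEUTRAL"), n_tokens, replace = TRUE)
  tokens <- mk_tokens(langs)
  spans <- list()
  i <- 1L
  while (i <= n_tokens) {
    if (runif(1) < 0.35) {
      len <- sample(1:min(3, n_tokens - i + 1L), 1)
      spans[[length(spans) + 1L]] <- data.frame(
        start = tokens$start[i], end = tokens$end[i + len - 1L],
        fine_type = sample(types, 1), stringsAsFactors = FALSE)
      i <- i + len
    } else i <- i + 1L
  }
  spans <- if (length(spans)) do.call(rbind, spans) else
    data.frame(start = integer(), end = integer(),
               fine_type = character(), stringsAsFactors = FALSE)
  list(tokens = tokens, spans = spans)
}

# random BILOU-looking label sequence (not necessarily valid)
rand_labels <- function(n = 15, types = c("Date", "City", "Doctor")) {
  pos <- sample(c("O", "B", "I", "L", "U"), n, replace = TRUE,
                prob = c(0.4, 0.15, 0.15, 0.15, 0.15))
  ifelse(pos == "O", "O", paste0(pos, "-", sample(types, n, replace = TRUE)))
}

# a tiny hand-built document: one train doc with known PHI
tiny_doc <- function(id = "d1", split = "TRAIN") {
  s1t <- "seen at Mercy Hospital on 2141/03/09\n"   # 37 chars
  s1 <- cm_sentence(paste0(id, "-s1"), s1t, start = 0L,
                    end = nchar(s1t))
  s2t <- "follow-up in Dr. 張家明 OPD"
  s2 <- cm_sentence(paste0(id, "-s2"), s2t, start = nchar(s1t),
                    end = nchar(s1t) + nchar(s2t))
  ann <- data.frame(
    start = c(8L, 26L, 37L + 17L),
    end = c(22L, 36L, 37L + 20L),
    fine_type = c("Hospital", "Date", "Doctor"),
    stringsAsFactors = FALSE
  )
  cm_document(id, list(s1, s2), ann, split)
}

# random small (gold, pred) corpus pair for metric-identity properties;
# regenerates until the gold test split carries at least one annotation
rand_gold_pred <- function(seed) {
  set.seed(seed)
  for (bump in 0:20) {
    cfg <- generator_config(n_train_docs = 1L, n_test_docs = 2L,
                            sentences_per_doc = c(2L, 4L),
                            oov_target = 0, ambiguity_rate = 0,
                            seed = seed + 100000L * bump)
    corpus <- generate_corpus(cfg)
    gold <- corpus_split(corpus, "TEST")
    if (sum(vapply(gold, function(d) nrow(d$annotations),
                   integer(1))) > 0) break
  }
  # perturb gold into predictions: drop, shift, retype, add spurious
  pred <- cm_corpus(lapply(unclass(gold), function(doc) {
    ann <- doc$annotations
    keep <- ann[runif(nrow(ann)) > 0.3, , drop = FALSE]
    if (nrow(keep)) {
      shift <- runif(nrow(keep)) < 0.4
      keep$start[shift] <- pmax(0L, keep$start[shift] -
                                  sample(0:2, sum(shift), replace = TRUE))
      retype <- runif(nrow(keep)) < 0.25
      keep$fine_type[retype] <- sample(phi_schema()$fine_types,
                                       sum(retype), replace = TRUE)
    }
    # spurious prediction in whitespace-free zone: reuse first tokens
    if (runif(1) < 0.5 && nchar(doc$text) > 4) {
      keep <- rbind(keep[, c("start", "end", "fine_type")],
                    data.frame(start = 0L, end = 2L,
                               fine_type = sample(phi_schema()$fine_types,
                                                  1)))
    }
    if (nrow(keep)) {
      keep <- keep[order(keep$start), , drop = FALSE]
      # drop overlapping predictions
      ok <- rep(TRUE, nrow(keep))
      last_end <- -1L
      for (i in seq_len(nrow(keep))) {
        if (keep$start[i] < last_end) ok[i] <- FALSE
        else last_end <- keep$end[i]
      }
      keep <- keep[ok, , drop = FALSE]
    }
    cm_document(doc$id, doc$sentences,
                keep[, c("start", "end", "fine_type")], doc$split)
  }))
  list(gold = gold, pred = pred)
}

report_counts <- function(report) {
  c(tp = sum(report$per_type$tp), fp = sum(report$per_type$fp),
    fn = sum(report$per_type$fn))
}
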