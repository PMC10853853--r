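#' @name llm_deid
#' @title Prompt-based zero-shot de-identification
#' @description
#' A constrained-prompt framework for recognizing PHI with a large
#' language model: a 4-part prompt (task instruction, sentence
#' introduction with PHI definitions, constraint statements, retrieval
#' message) is sent k times; the line-formatted responses are parsed into
#' typed candidates, majority voting retains candidates seen in at least
#' `min_count` runs, and the survivors are aligned back to character
#' spans in the input text.  The LLM itself is a backend contract; the
#' bundled mock backend is deterministic and offline.  Sending real
#' clinical text to an external LLM service has privacy implications and
#' is deliberately not part of the core package.
NULL

#' Prompt template for the de-identification prompt
#'
#' The four parts are concatenated in order; the sentence introduction
#' must contain the literal placeholder `<SENTENCE>` exactly once.
#' Defaults reconstruct the framework's structure: the task banner,
#' schema-derived PHI definitions, constraint clauses restricting output
#' to the defined types with no translation and a `TYPE: mention` line
#' format, and the retrieval message `"PHIs:"`.
#'
#' @param task_instruction,sentence_intro,constraint,retrieval_message
#'   The four prompt parts.
#' @param schema PHI schema used to render default definitions.
#' @return An object of class `prompt_template`.
#' @export
prompt_template <- function(task_instruction = "Extracting Private Information",
                            sentence_intro = NULL,
                            constraint = NULL,
                            retrieval_message = "PHIs:",
                            schema = phi_schema()) {
  if (is.null(sentence_intro)) {
    defs <- paste(sprintf("- %s: %s PHI of the %s category.",
                          toupper(schema$fine_types), schema$fine_types,
                          schema$fine_to_coarse[schema$fine_types]),
                  collapse = "\n")
    sentence_intro <- paste0(
      "Given the following clinical text:\n<SENTENCE>\n",
      "The protected health information (PHI) types of interest are:\n",
      defs, "\n")
  }
  if (is.null(constraint)) {
    constraint <- paste0(
      "Extract PHI from the given text based on the above definitions. ",
      "Only extract the defined PHI types. Do not translate extracted ",
      "text: report every mention exactly as it appears in the text. ",
      "Output one PHI per line in the format TYPE: mention.\n")
  }
  n_ph <- lengths(regmatches(sentence_intro,
                             gregexpr("<SENTENCE>", sentence_intro,
                                      fixed = TRUE)))
  if (n_ph != 1L) {
    stop("sentence_intro must contain the placeholder <SENTENCE> exactly once")
  }
  structure(list(task_instruction = task_instruction,
                 sentence_intro = sentence_intro,
                 constraint = constraint,
                 retrieval_message = retrieval_message),
            class = "prompt_template")
}

#' Assemble the final prompt for one sentence
#'
#' Substitutes the sentence text into the template's `<SENTENCE>` slot in
#' a single pass: text that itself contains the placeholder string is not
#' re-substituted.
#'
#' @param template A `prompt_template`.
#' @param sentence_text The input sentence.
#' @return A single prompt string.
#' @export
build_prompt <- function(template, sentence_text) {
  stopifnot(inherits(template, "prompt_template"))
  if (!nzchar(sentence_text)) {
    warning("building a prompt for an empty sentence")
  }
  intro <- template$sentence_intro
  pos <- regexpr("<SENTENCE>", intro, fixed = TRUE)
  intro <- paste0(substr(intro, 1, pos - 1), sentence_text,
                  substr(intro, pos + attr(pos, "match.length"),
                         nchar(intro)))
  paste0(template$task_instruction, "\n", intro, template$constraint,
         template$retrieval_message)
}

# alias table mapping LLM type strings (upper-cased, squeezed) to schema
# fine types
default_type_aliases <- function(schema = phi_schema()) {
  al <- c(
    stats::setNames(schema$fine_types, toupper(schema$fine_types)),
    "DOCTOR NAME" = "Doctor", "PATIENT NAME" = "Patient",
    "PERSON NAME" = "Person", "NAME" = "Person",
    "LOCATION" = "Named location", "GENERIC BUSINESS" = "Generic location",
    "ID" = "ID number", "MEDICAL RECORD NUMBER" = "Medical record"
  )
  al
}

#' Parse an LLM completion into PHI candidates
#'
#' Parsing is total: any byte string yields a (possibly empty) result.
#' Lines of the form `TYPE: mention` become candidates when `TYPE`
#' (case-insensitive, with documented aliases such as "DOCTOR NAME")
#' matches a schema fine type; lines with out-of-schema types (e.g.
#' "MEDICATION: haldol") are dropped and counted as constraint
#' violations.  Refusal phrases ("I'm sorry", "I apologize") yield an
#' empty candidate list flagged as a refusal.
#'
#' @param text Raw completion text.
#' @param schema PHI schema.
#' @param aliases Named character vector mapping upper-cased type strings
#'   to fine types.
#' @return list(candidates = data.frame(mention, fine_type), violations =
#'   integer count, refusal = logical).
#' @export
parse_response <- function(text, schema = phi_schema(),
                           aliases = default_type_aliases(schema)) {
  empty <- data.frame(mention = character(), fine_type = character(),
                      stringsAsFactors = FALSE)
  if (is.null(text) || is.na(text) || !nzchar(text)) {
    return(list(candidates = empty, violations = 0L, refusal = FALSE))
  }
  if (grepl("I'm sorry|I’m sorry|I apologize", text)) {
    return(list(candidates = empty, violations = 0L, refusal = TRUE))
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  cands <- list()
  violations <- 0L
  for (line in lines) {
    m <- regexec("^\\s*([^:]+?)\\s*:\\s*(.+?)\\s*$", line)
    g <- regmatches(line, m)[[1]]
    if (length(g) != 3) next
    key <- toupper(gsub("\\s+", " ", g[2]))
    ft <- unname(aliases[key])
    mention <- g[3]
    if (is.na(ft)) {
      violations <- violations + 1L
      next
    }
    if (!nzchar(mention)) next
    # multiple mentions may share one line, comma-separated
    parts <- trimws(strsplit(mention, ",", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    for (p in parts) {
      cands[[length(cands) + 1L]] <- data.frame(
        mention = p, fine_type = ft, stringsAsFactors = FALSE)
    }
  }
  cands <- if (length(cands)) do.call(rbind, cands) else empty
  list(candidates = cands, violations = violations, refusal = FALSE)
}

#' Align candidate mentions to character spans in the sentence
#'
#' Each mention is mapped to the leftmost not-yet-consumed exact
#' occurrence in the sentence text; a candidate listed twice consumes two
#' successive occurrences.  Mentions absent from the text (e.g. Chinese
#' PHI that the model translated into English) are dropped and counted.
#'
#' @param candidates data.frame(mention, fine_type).
#' @param sentence_text The sentence the candidates refer to.
#' @return list(annotations = data.frame(start, end, fine_type, mention),
#'   unalignable = integer count).
#' @export
align_candidates <- function(candidates, sentence_text) {
  consumed <- logical(nchar(sentence_text))
  out <- list()
  unalignable <- 0L
  if (nrow(candidates)) {
    for (i in seq_len(nrow(candidates))) {
      men <- candidates$mention[i]
      hits <- gregexpr(men, sentence_text, fixed = TRUE)[[1]]
      placed <- FALSE
      if (hits[1] != -1L) {
        for (h in hits) {
          idx <- h:(h + nchar(men) - 1L)
          if (!any(consumed[idx])) {
            consumed[idx] <- TRUE
            out[[length(out) + 1L]] <- data.frame(
              start = h - 1L, end = h - 1L + nchar(men),
              fine_type = candidates$fine_type[i], mention = men,
              stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
      }
      if (!placed) unalignable <- unalignable + 1L
    }
  }
  ann <- if (length(out)) do.call(rbind, out) else {
    data.frame(start = integer(), end = integer(), fine_type = character(),
               mention = character(), stringsAsFactors = FALSE)
  }
  ann <- ann[order(ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  list(annotations = ann, unalignable = unalignable)
}

#' Majority voting over repeated LLM queries
#'
#' A candidate's identity for voting is its (mention, fine type) pair:
#' runs may phrase span boundaries differently, so alignment happens once,
#' after the vote.  Identities present in at least `min_count` of the k
#' runs are retained (defaults k = 3, `min_count` = 2: kept if it
#' appeared at least twice).
#'
#' @param candidate_sets List of k data.frames (mention, fine_type), one
#'   per run.
#' @param min_count Minimum number of runs an identity must appear in.
#' @return data.frame(mention, fine_type) of retained identities, in
#'   first-appearance order.
#' @export
vote <- function(candidate_sets, min_count = 2L) {
  k <- length(candidate_sets)
  if (k < 1) stop("at least one candidate set is required")
  if (min_count > k) {
    stop("min_count (", min_count, ") exceeds the number of runs (", k, ")")
  }
  ids <- lapply(candidate_sets, function(df) {
    if (!nrow(df)) return(character(0))
    unique(paste0(df$fine_type, "\r", df$mention))
  })
  all_ids <- unlist(ids)
  first_order <- unique(all_ids)
  counts <- table(factor(all_ids, levels = first_order))
  keep <- first_order[counts[first_order] >= min_count]
  if (!length(keep)) {
    return(data.frame(mention = character(), fine_type = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keep, "\r", fixed = TRUE)
  data.frame(mention = vapply(parts, `[`, character(1), 2),
             fine_type = vapply(parts, `[`, character(1), 1),
             stringsAsFactors = FALSE)
}

#' LLM backend contract and deterministic mock
#'
#' A backend is a list with `complete(prompt, temperature, top_p, run)`
#' returning completion text.  `mock_llm_backend()` wraps a deterministic
#' function of (prompt, run index); it performs no network access.
#'
#' @param fn Function(prompt, run) -> completion text.
#' @param temperature,top_p Sampling parameters recorded with the backend
#'   (defaults 0.5/0.5, the framework's reference settings).
#' @return An object of class `llm_backend`.
#' @export
mock_llm_backend <- function(fn, temperature = 0.5, top_p = 0.5) {
  structure(list(complete = function(prompt, run = 1L) fn(prompt, run),
                 temperature = temperature, top_p = top_p,
                 deterministic = TRUE),
            class = "llm_backend")
}

#' De-identify one sentence with the prompt framework
#'
#' Composition: build the prompt, query the backend k times, parse each
#' response, vote, and align the retained candidates once.  A backend
#' failure on one run is tolerated (k effectively shrinks, with a
#' warning); if every run fails the result is empty and flagged.
#'
#' @param backend An `llm_backend`.
#' @param template A `prompt_template`.
#' @param sentence A `cm_sentence` (or raw text).
#' @param k Number of queries (default 3).
#' @param min_count Voting threshold (default 2).
#' @return list(annotations, log) where `log` records raw responses and
#'   per-run violation/refusal/unalignable counts.
#' @export
deid_sentence <- function(backend, template, sentence, k = 3L,
                          min_count = 2L) {
  text <- if (inherits(sentence, "cm_sentence")) sentence$text else sentence
  text <- sub("\n$", "", text)
  prompt <- build_prompt(template, text)
  responses <- vector("list", k)
  parsed <- vector("list", k)
  ok <- logical(k)
  for (run in seq_len(k)) {
    res <- tryCatch(backend$complete(prompt, run = run),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("backend failed on run ", run, ": ", conditionMessage(res))
      responses[[run]] <- NA_character_
      next
    }
    responses[[run]] <- res
    parsed[[run]] <- parse_response(res)
    ok[run] <- TRUE
  }
  all_failed <- !any(ok)
  cand_sets <- lapply(parsed[ok], function(p) p$candidates)
  voted <- if (length(cand_sets)) {
    vote(cand_sets, min_count = min(min_count, length(cand_sets)))
  } else {
    data.frame(mention = character(), fine_type = character(),
               stringsAsFactors = FALSE)
  }
  aligned <- align_candidates(voted, text)
  list(
    annotations = aligned$annotations,
    log = list(
      responses = responses,
      violations = sum(vapply(parsed[ok], function(p) p$violations,
                              integer(1))),
      refusals = sum(vapply(parsed[ok], function(p) p$refusal, logical(1))),
      unalignable = aligned$unalignable,
      runs_failed = sum(!ok),
      all_failed = all_failed
    )
  )
}

#' De-identify a corpus split with the prompt framework
#'
#' @param backend,template,k,min_count See [deid_sentence()].
#' @param corpus A `cm_corpus`.
#' @param split Split to process (default "TEST").
#' @return A `cm_corpus` with predicted annotations; attribute `"log"`
#'   aggregates per-sentence run logs.
#' @export
llm_deid_corpus <- function(backend, template, corpus, split = "TEST",
                            k = 3L, min_count = 2L) {
  logs <- list()
  docs <- lapply(unclass(corpus), function(doc) {
    if (doc$split != split) return(NULL)
    anns <- list()
    for (s in doc$sentences) {
      res <- deid_sentence(backend, template, s, k = k,
                           min_count = min_count)
      logs[[length(logs) + 1L]] <<- c(list(sentence = s$id), res$log)
      if (nrow(res$annotations)) {
        a <- res$annotations[, c("start", "end", "fine_type")]
        a$start <- a$start + s$start
        a$end <- a$end + s$start
        anns[[length(anns) + 1L]] <- a
      }
    }
    ann <- if (length(anns)) do.call(rbind, anns) else NULL
    with_annotations(doc, ann)
  })
  out <- cm_corpus(Filter(Negate(is.null), docs))
  attr(out, "log") <- logs
  out
}

#' A deterministic mock backend that reads gold annotations
#'
#' For offline end-to-end exercises of the framework: responses list the
#' gold PHI of the sentence in `TYPE: mention` lines, optionally
#' corrupted per run with constraint-violating noise lines
#' ("MEDICATION: ..."), run-specific spurious candidates (which majority
#' voting should remove) and refusals.  Deterministic given (corpus,
#' seed, run).
#'
#' @param corpus The gold `cm_corpus` the backend "knows".
#' @param noise_rate Probability that a run adds a run-specific spurious
#'   candidate line.
#' @param violation_rate Probability that a run adds an out-of-schema
#'   line.
#' @param refusal_rate Probability that a run refuses outright.
#' @param seed Integer seed.
#' @return An `llm_backend`.
#' @export
oracle_llm_backend <- function(corpus, noise_rate = 0.3,
                               violation_rate = 0.2, refusal_rate = 0,
                               seed = 1L) {
  # map sentence text -> gold annotation lines
  gold <- new.env(parent = emptyenv())
  for (doc in corpus) {
    for (s in doc$sentences) {
      ann <- sentence_annotations(doc, s)
      key <- sub("\n$", "", s$text)
      gold[[key]] <- ann
    }
  }
  noise_words <- c("haldol", "anxicam", "lorazepam", "insulin")
  mock_llm_backend(function(prompt, run) {
    # recover the sentence from the prompt deterministically
    m <- regexec("Given the following clinical text:\n(.*?)\n",
                 prompt, perl = TRUE)
    sent <- regmatches(prompt, m)[[1]][2]
    rng <- local_rng(seed + 131L * run +
                       utf8ToInt(substr(paste0(sent, " "), 1, 1)))
    if (rng$runif(1) < refusal_rate) {
      return("I'm sorry, but I can't assist with that request.")
    }
    ann <- gold[[sent]] %||%
      data.frame(fine_type = character(), mention = character())
    lines <- if (nrow(ann)) {
      sprintf("%s: %s", toupper(ann$fine_type), ann$mention)
    } else character(0)
    if (rng$runif(1) < violation_rate) {
      lines <- c(lines, sprintf("MEDICATION: %s",
                                noise_words[rng$sample_int(4L, 1L)]))
    }
    if (rng$runif(1) < noise_rate) {
      # run-specific spurious candidate: a word from the sentence tagged
      # with a type it does not have; appears in one run only
      toks <- tokenize_mixed(sent)
      if (nrow(toks)) {
        w <- toks$text[rng$sample_int(nrow(toks), 1L)]
        lines <- c(lines, sprintf("PROFESSION: %s~run%d", w, run))
      }
    }
    paste(lines, collapse = "\n")
  })
}
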