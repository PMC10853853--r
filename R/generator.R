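#' @name generator
#' @title Synthetic code-mixed discharge-summary generator
#' @description
#' Generates seeded corpora of annotated, code-mixed, discharge-summary-like
#' documents.  The stated world it emulates: four sentence categories
#' (English-only, Chinese-only, Chinese-English mixed, numeric/symbolic)
#' whose default proportions and per-category PHI-type frequencies follow
#' the training-set statistics of the corpus profile the package targets
#' (e.g. "Date" PHI concentrates in numeric/symbolic sentences, "Name" and
#' "Profession" in mixed sentences); 20 fine PHI types; ROC-calendar "mk"
#' date transliterations and Chinese-numeral dates; a configurable
#' out-of-vocabulary (OOV) rate realized by holding out a slice of every
#' lexicon for test-only sampling; and a configurable surface-ambiguity
#' rate.
NULL

# Table of per-category PHI counts in the emulated training corpus
# (fine type x sentence category), used to derive default expected
# PHI-type counts per sentence conditioned on category.
phi_count_table <- function() {
  m <- matrix(c(
    # EN,    ZH,   MIX,   NUM
    12436,  2146,  4530, 19850,  # Date
     2444,    21,   639,     0,  # Age
        9,   106,    42,     0,  # Patient
        8,     6,   128,     0,  # Person
       83,   161,  1169,     0,  # Doctor
       17,    11,   271,     0,  # Named location
       21,     3,    17,     0,  # Nationality
        6,     0,    10,     0,  # Region
      355,     6,   171,     0,  # Country
      196,    26,   510,     0,  # City
     1552,    73,  1915,     0,  # Hospital
     1616,  2278,   762,     0,  # Department
     1007,  1200,   248,     4,  # Room
        0,  1162,    25,     0,  # Number
       28,    15,   642,     0,  # School
      218,    37,   708,     0,  # Generic location
       12,     1,    50,     0,  # Market
      575,    82,  1566,     0,  # Profession
       43,    98,   170,     7,  # ID number
        1,    92,    19,     0   # Medical record
  ), nrow = 20, byrow = TRUE)
  dimnames(m) <- list(phi_schema()$fine_types, sentence_categories())
  m
}

category_sentence_totals <- function() {
  c(ENGLISH_ONLY = 20639, CHINESE_ONLY = 7526, MIXED = 13604,
    NUMERIC_SYMBOLIC = 19861)
}

default_phi_rate_matrix <- function() {
  sweep(phi_count_table(), 2, category_sentence_totals(), "/")
}

#' Generator configuration
#'
#' @param n_train_docs,n_test_docs Document counts per split.
#' @param sentences_per_doc Integer range `c(min, max)` of sentences per
#'   document.
#' @param category_mix Probability vector over the 4 sentence categories
#'   (names `ENGLISH_ONLY`, `CHINESE_ONLY`, `MIXED`, `NUMERIC_SYMBOLIC`);
#'   defaults to the emulated corpus's training-set proportions.
#' @param phi_rate_matrix 20 x 4 matrix of expected PHI-type counts per
#'   sentence conditioned on category; defaults to the emulated corpus's
#'   training-set counts normalized per category.
#' @param oov_target Fraction of test-split PHI mentions drawn from the
#'   held-out lexicon slice (so that they contain at least one token absent
#'   from the training vocabulary).
#' @param ambiguity_rate Fraction of lexicon entries duplicated under a
#'   second fine type, see [cm_lexicons()].
#' @param seed Integer seed; one seed drives a hierarchical stream per
#'   document.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_train_docs = 60L, n_test_docs = 20L,
                             sentences_per_doc = c(8L, 15L),
                             category_mix = NULL,
                             phi_rate_matrix = NULL,
                             oov_target = 0.5,
                             ambiguity_rate = 0.05,
                             seed = 1L) {
  if (is.null(category_mix)) {
    tot <- category_sentence_totals()
    category_mix <- tot / sum(tot)
  }
  if (is.null(phi_rate_matrix)) phi_rate_matrix <- default_phi_rate_matrix()
  if (n_train_docs < 1 || n_test_docs < 0) {
    stop("document counts must be positive")
  }
  if (abs(sum(category_mix) - 1) > 1e-9) {
    stop("category_mix must sum to 1")
  }
  if (any(category_mix < 0)) stop("category_mix entries must be >= 0")
  if (oov_target < 0 || oov_target > 1) stop("oov_target must be in [0, 1]")
  if (ambiguity_rate < 0 || ambiguity_rate > 1) {
    stop("ambiguity_rate must be in [0, 1]")
  }
  if (length(sentences_per_doc) != 2 ||
      sentences_per_doc[1] > sentences_per_doc[2] ||
      sentences_per_doc[1] < 1) {
    stop("sentences_per_doc must be c(min, max) with 1 <= min <= max")
  }
  stopifnot(nrow(phi_rate_matrix) == 20, ncol(phi_rate_matrix) == 4,
            all(phi_rate_matrix >= 0))
  structure(
    list(n_train_docs = as.integer(n_train_docs),
         n_test_docs = as.integer(n_test_docs),
         sentences_per_doc = as.integer(sentences_per_doc),
         category_mix = category_mix,
         phi_rate_matrix = phi_rate_matrix,
         oov_target = oov_target,
         ambiguity_rate = ambiguity_rate,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

category_scripts <- function(category) {
  switch(category,
         ENGLISH_ONLY = c("en", "num"),
         CHINESE_ONLY = c("zh", "num"),
         MIXED = c("en", "zh", "num"),
         NUMERIC_SYMBOLIC = "num")
}

# index the lexicon for fast sampling: lex_index[[fine_type]][[script]]
# is a list of row indices per slice
build_lex_index <- function(lex) {
  idx <- list()
  for (ft in unique(lex$fine_type)) {
    idx[[ft]] <- list()
    for (sc in unique(lex$script[lex$fine_type == ft])) {
      rows <- which(lex$fine_type == ft & lex$script == sc)
      idx[[ft]][[sc]] <- split(rows, lex$slice[rows])
    }
  }
  idx
}

sample_surface <- function(lex, idx, fine_type, scripts, slice, rng,
                           mixed_pref = FALSE) {
  avail <- intersect(scripts, names(idx[[fine_type]]))
  if (!length(avail)) return(NULL)
  if (mixed_pref && length(avail) > 1) {
    w <- c(en = 0.35, zh = 0.5, num = 0.15)[avail]
    u <- rng$runif(1)
    sc <- avail[findInterval(u * sum(w), cumsum(w), left.open = TRUE) + 1L]
  } else {
    sc <- avail[rng$sample_int(length(avail), 1L)]
  }
  rows <- idx[[fine_type]][[sc]][[slice]]
  if (!length(rows)) return(NULL)
  i <- rows[rng$sample_int(length(rows), 1L)]
  lex[i, , drop = FALSE]
}

#' Generate one synthetic sentence
#'
#' Realizes the requested PHI types inside a category-appropriate template:
#' filler segments drawn from per-category vocabulary plus one surface form
#' per requested PHI, at random positions.  Returned annotations are
#' token-aligned and correct by construction.
#'
#' @param category Sentence category.
#' @param phi_types Character vector of fine PHI types to realize (may
#'   repeat).
#' @param lex Lexicon data.frame from [cm_lexicons()].
#' @param rng Internal RNG stream (from a seeded generator run).
#' @param slice_picker Function(fine_type) returning "shared" or "heldout".
#' @param lex_index Optional precomputed index.
#' @return list(text, annotations, category) with sentence-relative
#'   0-based annotation offsets; `category` may have fallen back to MIXED
#'   when a requested type has no surface compatible with the requested
#'   category.
#' @export
generate_sentence <- function(category, phi_types, lex, rng,
                              slice_picker = function(ft) "shared",
                              lex_index = NULL) {
  stopifnot(category %in% sentence_categories())
  validate_fine_types(phi_types)
  if (is.null(lex_index)) lex_index <- build_lex_index(lex)
  fillers <- filler_inventory()
  fallback <- FALSE
  if (length(phi_types)) {
    ok <- vapply(phi_types, function(ft) {
      length(intersect(category_scripts(category),
                       names(lex_index[[ft]]))) > 0
    }, logical(1))
    if (!all(ok)) {
      fallback <- TRUE
      category <- "MIXED"
    }
  }
  scripts <- category_scripts(category)

  # filler segments
  n_fill <- 2L + rng$sample_int(5L, 1L)
  fill <- character(0)
  if (category == "ENGLISH_ONLY") {
    fill <- fillers$en[rng$sample_int(length(fillers$en), n_fill,
                                      replace = TRUE)]
  } else if (category == "CHINESE_ONLY") {
    fill <- fillers$zh[rng$sample_int(length(fillers$zh),
                                      max(2L, n_fill - 2L), replace = TRUE)]
  } else if (category == "MIXED") {
    n_en <- max(1L, n_fill - 2L)
    fill <- c(fillers$en[rng$sample_int(length(fillers$en), n_en,
                                        replace = TRUE)],
              fillers$zh[rng$sample_int(length(fillers$zh), 2L,
                                        replace = TRUE)])
  } else {
    fill <- fillers$num[rng$sample_int(length(fillers$num), n_fill,
                                       replace = TRUE)]
  }
  if (category %in% c("ENGLISH_ONLY", "CHINESE_ONLY", "MIXED") &&
      rng$runif(1) < 0.4) {
    fill <- c(fill, fillers$punct[rng$sample_int(length(fillers$punct), 1L)])
  }

  # PHI segments
  phi_rows <- lapply(phi_types, function(ft) {
    sample_surface(lex, lex_index, ft, scripts, slice_picker(ft), rng,
                   mixed_pref = category == "MIXED")
  })
  keep <- !vapply(phi_rows, is.null, logical(1))
  phi_rows <- phi_rows[keep]
  phi_types <- phi_types[keep]

  # interleave: random positions of PHI segments among fillers
  n_seg <- length(fill) + length(phi_rows)
  phi_pos <- if (length(phi_rows)) {
    sort(rng$sample_int(n_seg, length(phi_rows)))
  } else integer(0)
  segments <- character(n_seg)
  is_phi <- logical(n_seg)
  segments[phi_pos] <- vapply(phi_rows, function(r) r$surface, character(1))
  is_phi[phi_pos] <- TRUE
  segments[!is_phi] <- fill

  text <- paste(segments, collapse = " ")
  offs <- cumsum(c(0L, nchar(segments) + 1L))[seq_len(n_seg)]
  if (length(phi_pos)) {
    ann <- data.frame(
      start = offs[phi_pos],
      end = offs[phi_pos] + nchar(segments[phi_pos]),
      fine_type = phi_types,
      stringsAsFactors = FALSE
    )
  } else {
    ann <- data.frame(start = integer(), end = integer(),
                      fine_type = character(), stringsAsFactors = FALSE)
  }
  list(text = text, annotations = ann, category = category,
       fallback = fallback)
}

#' Generate a synthetic annotated corpus
#'
#' @param config A [generator_config()].
#' @return A `cm_corpus` with train and test documents, gold annotations,
#'   the resolved config in attribute `"generator_config"`, the lexicon in
#'   attribute `"lexicons"`, and a category-fallback count in attribute
#'   `"fallback_count"`.  Identical `(config, seed)` give identical output.
#' @examples
#' corp <- generate_corpus(generator_config(n_train_docs = 2,
#'                                          n_test_docs = 1, seed = 7))
#' corp
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  lex <- cm_lexicons(config$ambiguity_rate, seed = config$seed)
  if (config$oov_target > 0 && !any(lex$slice == "heldout")) {
    stop("infeasible config: oov_target > 0 requires held-out lexicon ",
         "entries, but the lexicon has none")
  }
  idx <- build_lex_index(lex)
  rng <- local_rng(config$seed)
  mix <- config$category_mix
  cats <- sentence_categories()
  rates <- config$phi_rate_matrix
  fallback_count <- 0L
  fine_types <- rownames(rates) %||% phi_schema()$fine_types

  make_doc <- function(doc_id, split, doc_rng) {
    n_sent <- config$sentences_per_doc[1] +
      doc_rng$sample_int(config$sentences_per_doc[2] -
                           config$sentences_per_doc[1] + 1L, 1L) - 1L
    slice_picker <- if (split == "TEST" && config$oov_target > 0) {
      function(ft) {
        if (doc_rng$runif(1) < config$oov_target) "heldout" else "shared"
      }
    } else function(ft) "shared"
    sents <- vector("list", n_sent)
    anns <- vector("list", n_sent)
    off <- 0L
    for (j in seq_len(n_sent)) {
      u <- doc_rng$runif(1)
      cat_j <- cats[findInterval(u, cumsum(mix), left.open = TRUE) + 1L]
      counts <- doc_rng$rpois(length(fine_types), rates[, cat_j])
      phi <- rep(fine_types, counts)
      g <- generate_sentence(cat_j, phi, lex, doc_rng,
                             slice_picker = slice_picker, lex_index = idx)
      if (g$fallback) fallback_count <<- fallback_count + 1L
      txt <- if (j < n_sent) paste0(g$text, "\n") else g$text
      sents[[j]] <- cm_sentence(sprintf("%s-s%d", doc_id, j), txt,
                                category = g$category,
                                start = off, end = off + nchar(txt))
      if (nrow(g$annotations)) {
        a <- g$annotations
        a$start <- a$start + off
        a$end <- a$end + off
        anns[[j]] <- a
      }
      off <- off + nchar(txt)
    }
    ann <- if (any(!vapply(anns, is.null, logical(1)))) {
      do.call(rbind, anns)
    } else NULL
    cm_document(doc_id, sents, ann, split)
  }

  docs <- vector("list", config$n_train_docs + config$n_test_docs)
  k <- 0L
  for (i in seq_len(config$n_train_docs)) {
    k <- k + 1L
    docs[[k]] <- make_doc(sprintf("train-%04d", i), "TRAIN", rng$derive(k))
  }
  for (i in seq_len(config$n_test_docs)) {
    k <- k + 1L
    docs[[k]] <- make_doc(sprintf("test-%04d", i), "TEST", rng$derive(k))
  }
  out <- cm_corpus(docs)
  attr(out, "generator_config") <- config
  attr(out, "lexicons") <- lex
  attr(out, "fallback_count") <- fallback_count
  out
}

#' Replace PHI mentions with same-type surrogates
#'
#' Every PHI mention in the document is replaced by a surrogate drawn from
#' the disjoint surrogate lexicon slice of the same fine type and, where
#' the original surface is recognized, the same lexical pattern class
#' (slashed numeric dates stay slashed, "mk" dates stay "mk", Chinese
#' surfaces stay Chinese).  Replacement is consistent within a document:
#' the same original mention always maps to the same surrogate.  Non-PHI
#' text is unchanged and all offsets are recomputed.
#'
#' @param doc A `cm_document` with gold annotations.
#' @param seed Integer seed for surrogate selection.
#' @param lex Lexicon to draw surrogates from (defaults to the packaged
#'   lexicon).
#' @return A new `cm_document`.
#' @export
resynthesize <- function(doc, seed = 1L, lex = cm_lexicons(0)) {
  if (!nrow(doc$annotations)) return(doc)
  rng <- local_rng(seed)
  sur <- lex[lex$slice == "surrogate", , drop = FALSE]
  origin <- lex[lex$slice != "surrogate", , drop = FALSE]
  mapping <- new.env(parent = emptyenv())
  surrogate_for <- function(fine_type, mention) {
    key <- paste0(fine_type, "\r", mention)
    hit <- mapping[[key]]
    if (!is.null(hit)) return(hit)
    pat <- origin$pattern[origin$fine_type == fine_type &
                            origin$surface == mention]
    cand <- if (length(pat)) {
      sur$surface[sur$fine_type == fine_type & sur$pattern == pat[1]]
    } else character(0)
    if (!length(cand)) cand <- sur$surface[sur$fine_type == fine_type]
    if (!length(cand)) cand <- mention  # no surrogate pool: keep as is
    val <- cand[rng$sample_int(length(cand), 1L)]
    mapping[[key]] <- val
    val
  }
  new_sents <- vector("list", length(doc$sentences))
  new_anns <- vector("list", length(doc$sentences))
  off <- 0L
  for (j in seq_along(doc$sentences)) {
    s <- doc$sentences[[j]]
    ann <- sentence_annotations(doc, s)
    if (nrow(ann)) {
      pieces <- character(0)
      new_rows <- ann
      cursor <- 0L
      new_off <- 0L
      for (i in seq_len(nrow(ann))) {
        pre <- substr0(s$text, cursor, ann$start[i])
        rep_txt <- surrogate_for(ann$fine_type[i], ann$mention[i])
        pieces <- c(pieces, pre, rep_txt)
        new_off <- new_off + nchar(pre)
        new_rows$start[i] <- new_off
        new_rows$end[i] <- new_off + nchar(rep_txt)
        new_off <- new_off + nchar(rep_txt)
        cursor <- ann$end[i]
      }
      pieces <- c(pieces, substr0(s$text, cursor, nchar(s$text)))
      txt <- paste(pieces, collapse = "")
      new_rows$start <- new_rows$start + off
      new_rows$end <- new_rows$end + off
      new_anns[[j]] <- new_rows[, c("start", "end", "fine_type")]
    } else {
      txt <- s$text
    }
    new_sents[[j]] <- cm_sentence(s$id, txt, start = off,
                                  end = off + nchar(txt))
    off <- off + nchar(txt)
  }
  ann <- if (any(!vapply(new_anns, is.null, logical(1)))) {
    do.call(rbind, new_anns)
  } else NULL
  cm_document(doc$id, new_sents, ann, doc$split)
}
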