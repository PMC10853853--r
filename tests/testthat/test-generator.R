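test_that("the default lexicon is role-consistent and covers the schema", {
  lx <- cm_lexicons(ambiguity_rate = 0)
  expect_setequal(unique(lx$fine_type), phi_schema()$fine_types)
  # every token text occupies exactly one (position, type) role
  conflicts <- cmdeid:::lexicon_role_conflicts(lx)
  expect_identical(nrow(conflicts), 0L)
  # >= 5 Chinese and >= 5 English surface patterns where applicable
  for (ft in c("Patient", "Person", "Doctor", "City", "Hospital",
               "Department", "School", "Generic location", "Market",
               "Profession")) {
    expect_gte(sum(lx$fine_type == ft & lx$script == "zh"), 5)
    expect_gte(sum(lx$fine_type == ft & lx$script == "en"), 5)
  }
  # slices are disjoint surface pools within type
  for (ft in unique(lx$fine_type)) {
    sub <- lx[lx$fine_type == ft, ]
    expect_identical(anyDuplicated(sub$surface), 0L)
  }
})

test_that("ambiguity injection shares surfaces across fine types", {
  lx <- cm_lexicons(ambiguity_rate = 0.1, seed = 3)
  dup <- lx[lx$slice == "shared", ]
  shared_surfaces <- names(which(table(dup$surface) > 1))
  expect_gt(length(shared_surfaces), 0)
  types_per_surface <- tapply(dup$fine_type, dup$surface,
                              function(x) length(unique(x)))
  expect_true(any(types_per_surface[shared_surfaces] >= 2))
})

test_that("generator config validation names the violated constraint", {
  expect_error(generator_config(category_mix = c(0.5, 0.5, 0.1, 0)),
               "sum to 1")
  expect_error(generator_config(oov_target = 1.2), "oov_target")
  expect_error(generator_config(n_train_docs = 0), "positive")
  expect_error(generator_config(sentences_per_doc = c(5, 2)),
               "sentences_per_doc")
})

test_that("same seed gives byte-identical corpora; different seeds differ", {
  cfg <- generator_config(n_train_docs = 4L, n_test_docs = 2L, seed = 7L)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1, c2)
  c3 <- generate_corpus(generator_config(n_train_docs = 4L,
                                         n_test_docs = 2L, seed = 8L))
  expect_false(identical(c1[[1]]$text, c3[[1]]$text))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_corpus(generator_config(n_train_docs = 1L,
                                             n_test_docs = 0L, seed = 9L)))
  expect_identical(.Random.seed, before)
})

test_that("degenerate category mix yields a single category", {
  cfg <- generator_config(
    n_train_docs = 5L, n_test_docs = 0L, seed = 2L,
    category_mix = c(ENGLISH_ONLY = 1, CHINESE_ONLY = 0, MIXED = 0,
                     NUMERIC_SYMBOLIC = 0))
  corp <- generate_corpus(cfg)
  cats <- vapply(cmdeid:::corpus_sentences(corp),
                 function(s) s$category, character(1))
  expect_true(all(cats == "ENGLISH_ONLY"))
  # declared categories agree with token-derived ones
  for (s in cmdeid:::corpus_sentences(corp)) {
    expect_identical(s$category, categorize_sentence(s))
  }
})

test_that("generated annotations satisfy the corpus invariants", {
  corp <- generate_corpus(generator_config(n_train_docs = 6L,
                                           n_test_docs = 3L, seed = 21L))
  for (doc in corp) {
    ann <- doc$annotations
    if (!nrow(ann)) next
    expect_identical(ann$mention,
                     substring(doc$text, ann$start + 1, ann$end))
    expect_true(all(ann$start[-1] >= ann$end[-nrow(ann)] | nrow(ann) == 1))
    # each annotation inside exactly one sentence, token-aligned
    for (i in seq_len(nrow(ann))) {
      k <- cmdeid:::sentence_of_annotation(doc, ann$start[i])
      s <- doc$sentences[[k]]
      expect_lte(ann$end[i], s$end)
      rel_s <- ann$start[i] - s$start
      rel_e <- ann$end[i] - s$start
      expect_true(rel_s %in% s$tokens$start)
      expect_true(rel_e %in% s$tokens$end)
    }
    # sentence spans partition the document
    starts <- vapply(doc$sentences, function(s) s$start, integer(1))
    ends <- vapply(doc$sentences, function(s) s$end, integer(1))
    expect_identical(starts, c(0L, ends[-length(ends)]))
    expect_identical(ends[length(ends)], nchar(doc$text))
  }
})

test_that("category proportions track the configured multinomial", {
  # 2,000 sentences is enough for a chi-square goodness-of-fit check
  cfg <- generator_config(n_train_docs = 200L, n_test_docs = 0L,
                          sentences_per_doc = c(10L, 10L), seed = 31L)
  corp <- generate_corpus(cfg)
  cats <- vapply(cmdeid:::corpus_sentences(corp),
                 function(s) s$category, character(1))
  obs <- table(factor(cats, levels = sentence_categories()))
  p <- stats::chisq.test(obs, p = cfg$category_mix)$p.value
  expect_gt(p, 0.01)
})

test_that("OOV targets are realized in the test split", {
  for (target in c(0, 0.6)) {
    cfg <- generator_config(n_train_docs = 150L, n_test_docs = 50L,
                            sentences_per_doc = c(8L, 8L),
                            oov_target = target, ambiguity_rate = 0,
                            seed = 17L)
    corp <- generate_corpus(cfg)
    vocab <- corpus_vocabulary(corp, "TRAIN")
    test_ann <- do.call(rbind, lapply(corpus_split(corp, "TEST"),
                                      function(d) d$annotations))
    part <- oov_partition(test_ann, vocab)
    expect_lt(abs(mean(part$oov) - target), 0.05)
  }
})

test_that("resynthesis replaces mentions consistently and preserves structure", {
  corp <- generate_corpus(generator_config(n_train_docs = 8L,
                                           n_test_docs = 0L, seed = 11L,
                                           ambiguity_rate = 0))
  lex <- attr(corp, "lexicons")
  sur_surfaces <- lex$surface[lex$slice == "surrogate"]
  for (doc in corp) {
    new <- resynthesize(doc, seed = 5L, lex = lex)
    expect_identical(nrow(new$annotations), nrow(doc$annotations))
    expect_identical(new$annotations$fine_type, doc$annotations$fine_type)
    expect_identical(new$annotations$mention,
                     substring(new$text, new$annotations$start + 1,
                               new$annotations$end))
    if (nrow(doc$annotations)) {
      # same original mention -> same surrogate, drawn from the
      # surrogate slice
      map <- tapply(new$annotations$mention,
                    paste0(doc$annotations$fine_type, "|",
                           doc$annotations$mention),
                    function(x) length(unique(x)))
      expect_true(all(map == 1))
      expect_true(all(new$annotations$mention %in% sur_surfaces))
    }
    # non-PHI text unchanged: masking both docs' PHI yields equal text
    mask <- function(d) {
      txt <- d$text
      for (i in rev(seq_len(nrow(d$annotations)))) {
        txt <- paste0(substr(txt, 1, d$annotations$start[i]), "#",
                      substr(txt, d$annotations$end[i] + 1, nchar(txt)))
      }
      txt
    }
    expect_identical(mask(doc), mask(new))
  }
  # pattern-class preservation: slashed dates stay slashed
  doc <- corp[[1]]
  dates <- doc$annotations[doc$annotations$fine_type == "Date", ]
  if (nrow(dates)) {
    new <- resynthesize(doc, seed = 5L, lex = lex)
    nd <- new$annotations[new$annotations$fine_type == "Date", ]
    for (i in seq_len(nrow(dates))) {
      if (grepl("/", dates$mention[i])) expect_match(nd$mention[i], "/")
      if (startsWith(dates$mention[i], "mk")) {
        expect_match(nd$mention[i], "^mk")
      }
    }
  }
  # a doc with no PHI is returned unchanged
  empty <- cm_document("e", list(cm_sentence("e-s1", "no phi here")),
                       NULL, "TRAIN")
  expect_identical(resynthesize(empty, seed = 1L), empty)
})

test_that("per-category PHI-type histograms converge to the rate matrix", {
  cfg <- generator_config(n_train_docs = 300L, n_test_docs = 0L,
                          sentences_per_doc = c(10L, 10L), seed = 41L)
  corp <- generate_corpus(cfg)
  dist <- phi_distribution(corp)[, , "TRAIN"]
  rates <- cfg$phi_rate_matrix
  cats <- vapply(cmdeid:::corpus_sentences(corp),
                 function(s) s$category, character(1))
  n_cat <- table(factor(cats, levels = sentence_categories()))
  for (cat_ in c("ENGLISH_ONLY", "MIXED")) {   # the two largest categories
    want <- rates[, cat_] / sum(rates[, cat_])
    got <- dist[, cat_] / sum(dist[, cat_])
    tv <- 0.5 * sum(abs(want - got))
    expect_lt(tv, 0.05)
  }
})
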