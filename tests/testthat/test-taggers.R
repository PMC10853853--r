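# build a tiny training corpus from explicit sentence/annotation pairs
corpus_from <- function(sents_ann, split = "TRAIN", id = "d1") {
  off <- 0L
  sents <- list()
  anns <- list()
  n <- length(sents_ann)
  for (i in seq_len(n)) {
    txt <- sents_ann[[i]]$text
    if (i < n) txt <- paste0(txt, "\n")
    s <- cm_sentence(sprintf("%s-s%d", id, i), txt, start = off,
                     end = off + nchar(txt))
    sents[[i]] <- s
    a <- sents_ann[[i]]$ann
    if (!is.null(a) && nrow(a)) {
      a$start <- a$start + off
      a$end <- a$end + off
      anns[[length(anns) + 1L]] <- a
    }
    off <- off + nchar(txt)
  }
  ann <- if (length(anns)) do.call(rbind, anns) else NULL
  cm_corpus(list(cm_document(id, sents, ann, split)))
}

span <- function(start, end, ft) {
  data.frame(start = start, end = end, fine_type = ft,
             stringsAsFactors = FALSE)
}

test_that("dictionary stores the most frequent tag per token", {
  # "台" seen 3x as B-Hospital (台大醫院-like 2-token spans) and 1x B-City
  corp <- corpus_from(list(
    list(text = "台北", ann = span(0, 2, "Hospital")),
    list(text = "台中", ann = span(0, 2, "Hospital")),
    list(text = "台南", ann = span(0, 2, "Hospital")),
    list(text = "台東", ann = span(0, 2, "City"))
  ))
  dict <- build_dictionary(corp)
  expect_identical(unname(dict$entries[["台"]]), "B-Hospital")
  # a token only ever seen as O maps to O
  corp2 <- corpus_from(list(list(text = "plain words", ann = NULL)))
  dict2 <- build_dictionary(corp2)
  expect_identical(unname(dict2$entries[["plain"]]), "O")
  # empty training set -> empty dictionary
  empty <- cm_corpus(list(cm_document("t", list(cm_sentence("t-s1", "x")),
                                      NULL, "TEST")))
  expect_length(build_dictionary(empty)$entries, 0)
})

test_that("dictionary ties break lexicographically and are recorded", {
  corp <- corpus_from(list(
    list(text = "甲", ann = span(0, 1, "City")),
    list(text = "甲", ann = span(0, 1, "City")),
    list(text = "甲", ann = span(0, 1, "Hospital")),
    list(text = "甲", ann = span(0, 1, "Hospital"))
  ))
  dict <- build_dictionary(corp)
  expect_identical(unname(dict$entries[["甲"]]), "U-City")  # "U-City" < "U-Hospital"
  expect_true("甲" %in% dict$ties)
})

test_that("dictionary keys are case-sensitive unless folding is requested", {
  corp <- corpus_from(list(
    list(text = "NKUST campus", ann = span(0, 5, "School"))))
  dict <- build_dictionary(corp)
  s <- cm_sentence("x", "nkust NKUST")
  expect_identical(dba_predict(dict, s), c("O", "U-School"))
  dict_cf <- build_dictionary(corp, case_fold = TRUE)
  # both case variants hit the folded entry; two adjacent single-token
  # entities are a valid BILOU sequence and stay separate
  expect_identical(dba_predict(dict_cf, s), c("U-School", "U-School"))
})

test_that("dba lookup maps unseen tokens to O and repairs its output", {
  corp <- corpus_from(list(
    list(text = "visited 台北 clinic",
         ann = span(8, 10, "City"))))
  dict <- build_dictionary(corp)
  # all tokens unseen -> all O
  expect_identical(dba_predict(dict, cm_sentence("x", "totally new words")),
                   rep("O", 3))
  # memorization: an unambiguous training sentence is recovered exactly
  s <- cm_sentence("x", "visited 台北 clinic")
  expect_identical(dba_predict(dict, s),
                   c("O", "B-City", "L-City", "O"))
  # a lone I-label from lookup is repaired to a valid sequence
  dict$entries[["clinic"]] <- "I-Date"
  expect_identical(dba_predict(dict, cm_sentence("x", "clinic")), "U-Date")
})

test_that("DBA reaches micro-F 1.0 when test = train and no token is ambiguous", {
  cfg <- generator_config(n_train_docs = 20L, n_test_docs = 0L,
                          ambiguity_rate = 0, seed = 19L)
  corp <- generate_corpus(cfg)
  fitted <- fit_tagger(dba_tagger(), corp)
  pred <- predict_corpus(fitted, corp, split = "TRAIN")
  rep <- score(corp, pred, criterion = "exact")
  expect_identical(rep$micro$f, 1)
  expect_identical(rep$macro_f, 1)
})

test_that("DBA micro-recall degrades monotonically with the OOV rate", {
  fs <- vapply(c(0, 0.3, 0.6), function(oov) {
    cfg <- generator_config(n_train_docs = 40L, n_test_docs = 15L,
                            oov_target = oov, ambiguity_rate = 0,
                            seed = 23L)
    corp <- generate_corpus(cfg)
    fitted <- fit_tagger(dba_tagger(), corp)
    pred <- predict_corpus(fitted, corp, "TEST")
    score(corpus_split(corp, "TEST"), pred)$micro$recall
  }, numeric(1))
  expect_true(all(diff(fs) < 0))
})

test_that("any tagger's decoded output satisfies the span invariants", {
  corp <- generate_corpus(generator_config(n_train_docs = 10L,
                                           n_test_docs = 5L, seed = 29L))
  pred <- predict_corpus(fit_tagger(dba_tagger(), corp), corp, "TEST")
  for (doc in pred) {
    ann <- doc$annotations
    if (!nrow(ann)) next
    expect_identical(ann$mention,
                     substring(doc$text, ann$start + 1, ann$end))
    expect_true(nrow(ann) == 1 ||
                  all(ann$start[-1] >= ann$end[-nrow(ann)]))
    validate_fine_types(ann$fine_type)
  }
})
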