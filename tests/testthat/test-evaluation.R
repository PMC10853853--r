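ann_df <- function(start, end, ft) {
  data.frame(start = start, end = end, fine_type = ft,
             stringsAsFactors = FALSE)
}

test_that("match_spans distinguishes exact from approximate criteria", {
  gold <- ann_df(10L, 20L, "Doctor")
  pred <- ann_df(12L, 20L, "Doctor")
  expect_identical(nrow(match_spans(gold, pred, "exact")$pairs), 0L)
  expect_identical(nrow(match_spans(gold, pred, "approximate")$pairs), 1L)
  # identical spans, different types never match at fine level
  pred2 <- ann_df(10L, 20L, "Patient")
  expect_identical(nrow(match_spans(gold, pred2, "exact")$pairs), 0L)
  expect_identical(nrow(match_spans(gold, pred2, "approximate")$pairs), 0L)
  # disjoint spans are FP + FN
  pred3 <- ann_df(30L, 35L, "Doctor")
  mm <- match_spans(gold, pred3, "approximate")
  expect_identical(mm$unmatched_gold, 1L)
  expect_identical(mm$unmatched_pred, 1L)
  # each side used at most once; higher overlap wins
  gold2 <- ann_df(c(0L, 10L), c(8L, 20L), c("City", "City"))
  pred4 <- ann_df(6L, 20L, "City")  # overlaps both golds
  mm <- match_spans(gold2, pred4, "approximate")
  expect_identical(mm$pairs$gold, 2L)  # 10 chars overlap beats 2
  # configurable minimum-overlap fraction
  mm <- match_spans(gold, pred, "approximate", min_overlap = 0.9)
  expect_identical(nrow(mm$pairs), 0L)
})

test_that("score computes the textbook precision/recall/F arithmetic", {
  gold <- cm_corpus(list(tiny_doc("d1", "TEST")))
  # predict Hospital correctly, add one spurious Hospital: TP=1 FP=1 FN=0
  pred <- cm_corpus(list(cm_document(
    "d1", gold[["d1"]]$sentences,
    ann_df(c(8L, 0L), c(22L, 4L), c("Hospital", "Hospital")), "TEST")))
  rep <- score(gold, pred, criterion = "exact")
  hosp <- rep$per_type[rep$per_type$fine_type == "Hospital", ]
  expect_equal(hosp$precision, 0.5)
  expect_equal(hosp$recall, 1.0)
  expect_equal(hosp$f, 2 / 3)
  # perfect predictions: micro F = macro F = 1, for every present type
  perfect <- score(gold, gold)
  expect_identical(perfect$micro$f, 1)
  expect_identical(perfect$macro_f, 1)
  present <- perfect$per_type$tp + perfect$per_type$fn > 0
  expect_true(all(perfect$per_type$f[present] == 1))
})

test_that("coarse-grained mapping credits same-coarse confusions", {
  gold <- cm_corpus(list(tiny_doc("d1", "TEST")))
  # City predicted where gold says Hospital (both Location)
  pred <- cm_corpus(list(cm_document(
    "d1", gold[["d1"]]$sentences, ann_df(8L, 22L, "City"), "TEST")))
  fine <- score(gold, pred, criterion = "exact", level = "fine")
  expect_identical(sum(fine$per_type$tp), 0L)
  coarse <- score(gold, pred, criterion = "exact", level = "coarse_mapped")
  loc <- coarse$per_type[coarse$per_type$fine_type == "Location", ]
  expect_identical(loc$tp, 1L)
})

test_that("macro averaging only covers types present in gold", {
  gold <- cm_corpus(list(cm_document(
    "d1", list(cm_sentence("d1-s1", "seen at Mercy Hospital")),
    ann_df(8L, 22L, "Hospital"), "TEST")))
  rep <- score(gold, gold)
  expect_identical(rep$macro_f, 1)  # not dragged down by 19 absent types
})

test_that("metric identities hold over random (gold, pred) corpora", {
  for (seed in 1:60) {
    gp <- rand_gold_pred(seed)
    g <- gp$gold; p <- gp$pred
    # symmetry
    expect_identical(score(g, g)$micro$f, 1)
    exact <- score(g, p, "exact")
    approx <- score(g, p, "approximate")
    coarse <- score(g, p, "exact", level = "coarse_mapped")
    # matching monotonicity
    expect_gte(approx$micro$f, exact$micro$f)
    # mapping monotonicity
    expect_gte(coarse$micro$f, exact$micro$f)
    # micro F is the harmonic mean of micro P and R when both nonzero
    if (exact$micro$precision > 0 && exact$micro$recall > 0) {
      expect_equal(exact$micro$f,
                   2 * exact$micro$precision * exact$micro$recall /
                     (exact$micro$precision + exact$micro$recall))
    }
    # stratum conservation for every stratifier
    glob <- report_counts(exact)
    for (st in c("sentence_category", "cmi_bin", "oov")) {
      reps <- score_stratified(g, p, stratifier = st, criterion = "exact")
      pooled <- Reduce(`+`, lapply(reps, report_counts))
      expect_identical(pooled, glob)
    }
  }
})

test_that("sentence error rate counts any-token errors per CMI bin", {
  corp <- generate_corpus(generator_config(n_train_docs = 4L,
                                           n_test_docs = 4L, seed = 59L))
  gold <- corpus_split(corp, "TEST")
  # perfect predictions -> all rates 0
  ser <- sentence_error_rate(gold, gold)
  expect_true(all(ser$rate == 0))
  expect_identical(attr(ser, "overall"), 0)
  # empty predictions: a sentence is wrong iff it has gold PHI,
  # regardless of how many of its tokens are wrong (any-token rule)
  empty_pred <- cm_corpus(lapply(unclass(gold), function(d) {
    cm_document(d$id, d$sentences, NULL, d$split)
  }))
  ser <- sentence_error_rate(gold, empty_pred)
  n_phi_sent <- sum(vapply(unclass(gold), function(d) {
    sum(vapply(d$sentences, function(s) {
      nrow(sentence_annotations(d, s)) > 0
    }, logical(1)))
  }, integer(1)))
  expect_identical(sum(ser$wrong), n_phi_sent)
  # bin-weighted mean equals the overall rate
  expect_equal(sum(ser$rate * ser$n) / sum(ser$n), attr(ser, "overall"))
  # empty bins are absent, not zero
  expect_true(all(ser$n > 0))
})

test_that("oov partition implements the at-least-one-unseen-token rule", {
  mentions <- data.frame(
    mention = c("Mercy Hospital", "Mercy Clinic", "台北"),
    fine_type = c("Hospital", "Hospital", "City"),
    stringsAsFactors = FALSE)
  vocab <- c("Mercy", "Hospital", "台", "北")
  part <- oov_partition(mentions, vocab)
  expect_identical(part$oov, c(FALSE, TRUE, FALSE))
  loc <- part$rates[part$rates$coarse_type == "Location", ]
  expect_equal(loc$oov_rate, 1 / 3)
  # empty vocabulary makes every mention OOV
  part <- oov_partition(mentions, character(0))
  expect_true(all(part$oov))
  expect_equal(part$rates$oov_rate[part$rates$coarse_type == "Location"], 1)
})

test_that("stratified scoring matches the global report on a single stratum", {
  cfg <- generator_config(
    n_train_docs = 2L, n_test_docs = 2L, seed = 61L,
    category_mix = c(ENGLISH_ONLY = 1, CHINESE_ONLY = 0, MIXED = 0,
                     NUMERIC_SYMBOLIC = 0))
  corp <- generate_corpus(cfg)
  gold <- corpus_split(corp, "TEST")
  pred <- predict_corpus(fit_tagger(dba_tagger(), corp), corp)
  reps <- score_stratified(gold, pred, "sentence_category")
  expect_identical(names(reps), "ENGLISH_ONLY")
  glob <- score(gold, pred)
  expect_identical(reps[[1]]$per_type, glob$per_type)
  expect_identical(reps[[1]]$micro, glob$micro)
})

test_that("phi_distribution counts per type, category and split", {
  doc <- tiny_doc("d1")
  corp <- cm_corpus(list(doc))
  dist <- phi_distribution(corp)
  expect_identical(sum(dist), nrow(doc$annotations))
  expect_identical(unname(dist["Date", "ENGLISH_ONLY", "TRAIN"]), 1L)
  expect_identical(unname(dist["Doctor", "MIXED", "TRAIN"]), 1L)
  expect_identical(unname(dist["Hospital", "ENGLISH_ONLY", "TRAIN"]), 1L)
})

test_that("document-id mismatches are reported", {
  g <- cm_corpus(list(tiny_doc("a", "TEST")))
  p <- cm_corpus(list(tiny_doc("b", "TEST")))
  expect_error(score(g, p), "missing")
})
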