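test_that("the default template has four parts and one placeholder", {
  tpl <- prompt_template()
  expect_identical(tpl$task_instruction, "Extracting Private Information")
  expect_identical(tpl$retrieval_message, "PHIs:")
  expect_identical(
    lengths(regmatches(tpl$sentence_intro,
                       gregexpr("<SENTENCE>", tpl$sentence_intro,
                                fixed = TRUE))), 1L)
  expect_error(prompt_template(sentence_intro = "no placeholder here"),
               "exactly once")
})

test_that("build_prompt substitutes the slot verbatim, single-pass", {
  tpl <- prompt_template(task_instruction = "A",
                         sentence_intro = "B(<SENTENCE>)",
                         constraint = "C", retrieval_message = "D")
  expect_identical(build_prompt(tpl, "x"), "A\nB(x)CD")
  # a sentence containing the placeholder literally is not re-substituted
  out <- build_prompt(tpl, "evil <SENTENCE> text")
  expect_identical(out, "A\nB(evil <SENTENCE> text)CD")
  expect_warning(build_prompt(tpl, ""), "empty")
})

test_that("parse_response accepts schema types and aliases, drops violations", {
  res <- parse_response("DOCTOR NAME: 張家明")
  expect_identical(res$candidates$mention, "張家明")
  expect_identical(res$candidates$fine_type, "Doctor")
  # out-of-schema entity types count as constraint violations
  res <- parse_response("MEDICATION: haldol, anxicam\nDOSE: 1 amp")
  expect_identical(nrow(res$candidates), 0L)
  expect_identical(res$violations, 2L)
  # refusals yield an empty flagged result
  res <- parse_response("I'm sorry, but I can't assist with that request.")
  expect_identical(nrow(res$candidates), 0L)
  expect_true(res$refusal)
  # comma-separated mentions on one line fan out
  res <- parse_response("CITY: Taipei, Tainan")
  expect_identical(res$candidates$mention, c("Taipei", "Tainan"))
  # case-insensitive type match
  res <- parse_response("hospital: Mercy Hospital")
  expect_identical(res$candidates$fine_type, "Hospital")
})

test_that("parse_response is total over arbitrary byte strings", {
  set.seed(3)
  for (i in 1:200) {
    bytes <- rawToChar(as.raw(sample(c(9:13, 32:126), sample(0:60, 1),
                                     replace = TRUE)))
    expect_no_error(parse_response(bytes))
  }
  expect_no_error(parse_response(NA))
  expect_no_error(parse_response(""))
  expect_no_error(parse_response(": : : ::\n\n:\n"))
})

test_that("alignment is leftmost-unconsumed with repeat bookkeeping", {
  txt <- "去 台北 又回 台北 one"
  cand <- data.frame(mention = c("台北", "台北"),
                     fine_type = c("City", "City"),
                     stringsAsFactors = FALSE)
  res <- align_candidates(cand, txt)
  expect_identical(res$annotations$start, c(2L, 8L))
  expect_identical(res$unalignable, 0L)
  # absent mention dropped and counted
  res <- align_candidates(data.frame(mention = "Taipei",
                                     fine_type = "City"), txt)
  expect_identical(nrow(res$annotations), 0L)
  expect_identical(res$unalignable, 1L)
})

test_that("voting keeps identities seen in at least min_count runs", {
  # exhaustive over all presence patterns across 3 runs
  for (mask in 1:7) {
    present <- as.logical(bitwAnd(mask, c(1L, 2L, 4L)))
    sets <- lapply(present, function(p) {
      if (p) data.frame(mention = "x", fine_type = "City")
      else data.frame(mention = character(), fine_type = character())
    })
    kept <- nrow(vote(sets, min_count = 2L)) == 1L
    expect_identical(kept, sum(present) >= 2)
  }
  # duplicates within one run count once toward the vote
  twice <- data.frame(mention = c("x", "x"), fine_type = c("City", "City"))
  none <- data.frame(mention = character(), fine_type = character())
  expect_identical(nrow(vote(list(twice, none, none), 2L)), 0L)
  expect_error(vote(list(none), min_count = 2), "exceeds")
})

test_that("voting is monotone in min_count and k", {
  set.seed(9)
  mk_set <- function() {
    n <- sample(0:4, 1)
    data.frame(mention = sample(letters[1:5], n, replace = TRUE),
               fine_type = sample(c("City", "Doctor"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  key <- function(df) {
    if (!nrow(df)) character(0) else paste0(df$fine_type, ":", df$mention)
  }
  for (i in 1:50) {
    sets <- replicate(4, mk_set(), simplify = FALSE)
    v1 <- key(vote(sets[1:3], 1L)); v2 <- key(vote(sets[1:3], 2L))
    expect_true(all(v2 %in% v1))          # lowering min_count only adds
    v3 <- key(vote(sets, 2L))
    expect_true(all(v2 %in% v3))          # more runs never remove
  }
})

test_that("deid_sentence filters run-specific noise via the vote", {
  s <- cm_sentence("s", "seen at 台北 by Vera Crawford")
  stable <- "CITY: 台北\nDOCTOR: Vera Crawford"
  backend <- mock_llm_backend(function(prompt, run) {
    if (run < 3) stable else paste0(stable, "\nMEDICATION: haldol\n",
                                    "PROFESSION: seen")
  })
  res <- deid_sentence(backend, prompt_template(), s)
  expect_identical(res$annotations$fine_type, c("City", "Doctor"))
  expect_identical(res$annotations$mention, c("台北", "Vera Crawford"))
  expect_identical(res$log$violations, 1L)   # the MEDICATION line
  # "PROFESSION: seen" parsed fine but appeared in 1 run -> voted out
  expect_false("Profession" %in% res$annotations$fine_type)
})

test_that("all-refusal and degenerate single-shot behaviors", {
  s <- cm_sentence("s", "seen at 台北")
  refuser <- mock_llm_backend(function(prompt, run) "I apologize")
  res <- deid_sentence(refuser, prompt_template(), s)
  expect_identical(nrow(res$annotations), 0L)
  expect_identical(res$log$refusals, 3L)
  # k = 1, min_count = 1 equals the aligned parse of a single response
  one <- mock_llm_backend(function(prompt, run) "CITY: 台北")
  res <- deid_sentence(one, prompt_template(), s, k = 1L, min_count = 1L)
  expect_identical(res$annotations$mention, "台北")
  # backend failure on one run shrinks k with a warning
  flaky <- mock_llm_backend(function(prompt, run) {
    if (run == 2) stop("boom") else "CITY: 台北"
  })
  expect_warning(res <- deid_sentence(flaky, prompt_template(), s),
                 "run 2")
  expect_identical(res$annotations$mention, "台北")
  expect_identical(res$log$runs_failed, 1L)
})

test_that("voting improves precision over single runs under disjoint noise", {
  set.seed(31)
  truth <- data.frame(mention = c("台北", "Vera"),
                      fine_type = c("City", "Doctor"),
                      stringsAsFactors = FALSE)
  key <- function(df) {
    if (!nrow(df)) character(0) else paste0(df$fine_type, ":", df$mention)
  }
  prec <- function(df) {
    if (!nrow(df)) return(0)
    mean(key(df) %in% key(truth))
  }
  for (i in 1:25) {
    runs <- lapply(1:3, function(r) {
      noise <- data.frame(
        mention = paste0("junk", r, "_", seq_len(sample(1:3, 1))),
        fine_type = "City", stringsAsFactors = FALSE)
      rbind(truth, noise)
    })
    voted <- vote(runs, 2L)
    expect_gte(prec(voted), max(vapply(runs, prec, numeric(1))))
    expect_identical(sort(key(voted)), sort(key(truth)))
  }
})

test_that("the oracle mock backend drives the framework to high precision", {
  corp <- generate_corpus(generator_config(n_train_docs = 2L,
                                           n_test_docs = 4L, seed = 53L))
  backend <- oracle_llm_backend(corp, noise_rate = 0.5,
                                violation_rate = 0.5, seed = 7L)
  pred <- llm_deid_corpus(backend, prompt_template(), corp)
  rep <- score(corpus_split(corp, "TEST"), pred,
               criterion = "approximate")
  expect_gt(rep$micro$recall, 0.95)
  expect_gt(rep$micro$precision, 0.95)
})
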