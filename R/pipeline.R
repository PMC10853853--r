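#' @name pipeline
#' @title End-to-end reproducible runs
#' @description
#' Composes generate -> profile -> (train/predict | normalize+predict |
#' llm-deid) -> evaluate into one seeded run whose artifacts land in a run
#' directory together with the resolved configuration, so that every
#' artifact is regenerable from the echoed config alone.
NULL

#' Run configuration
#'
#' @param seed Top-level integer seed, fanned out per stage.
#' @param generator A [generator_config()] (its seed is overridden by
#'   `seed`).
#' @param tagger "dba" or a `cm_tagger` object.
#' @param translator "none", "identity", or a `cm_translator`; when not
#'   "none" both splits are normalized before training/prediction.
#' @param llm `NULL` or a list with fields `k`, `min_count`, `noise_rate`,
#'   `violation_rate`: run the mock-backed LLM framework instead of the
#'   tagger.
#' @param criterion,level,stratifiers Evaluation settings.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       generator = generator_config(seed = seed),
                       tagger = "dba",
                       translator = "none",
                       llm = NULL,
                       criterion = "exact",
                       level = "fine",
                       stratifiers = c("sentence_category", "cmi_bin",
                                       "oov")) {
  generator$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), generator = generator,
                 tagger = tagger, translator = translator, llm = llm,
                 criterion = criterion, level = level,
                 stratifiers = stratifiers),
            class = "run_config")
}

resolve_translator <- function(x) {
  if (inherits(x, "cm_translator")) return(x)
  switch(x,
         none = NULL,
         identity = identity_translator(),
         stop("unknown translator: ", x))
}

resolve_tagger <- function(x) {
  if (inherits(x, "cm_tagger")) return(x)
  switch(x,
         dba = dba_tagger(),
         stop("unknown tagger: ", x))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

report_rows <- function(report, stratum = NA_character_) {
  pt <- report$per_type
  pt$stratum <- stratum
  extra <- data.frame(
    fine_type = c("micro", "macro"),
    tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
    precision = c(report$micro$precision, NA),
    recall = c(report$micro$recall, NA),
    f = c(report$micro$f, report$macro_f),
    stratum = stratum, stringsAsFactors = FALSE
  )
  rbind(pt, extra)
}

#' Execute a configured run
#'
#' Stages are logged with timings; any stage failure raises an error
#' naming the stage (partial artifacts are preserved in `out_dir`).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, created if needed.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the corpus, predictions, profile and
#'   evaluation reports, plus `paths` of written artifacts.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    say(sprintf("[%s] done in %.2fs", name,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  paths <- list(config = file.path(out_dir, "config.json"))
  cfg_json <- list(
    seed = config$seed,
    generator = config$generator[setdiff(names(config$generator),
                                         "phi_rate_matrix")],
    tagger = if (is.character(config$tagger)) config$tagger else "custom",
    translator = if (is.character(config$translator)) config$translator
                 else "custom",
    llm = config$llm, criterion = config$criterion, level = config$level,
    stratifiers = config$stratifiers
  )
  jsonlite::write_json(cfg_json, paths$config, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  corpus <- stage("generate", generate_corpus(config$generator))
  paths$corpus <- file.path(out_dir, "corpus.json")
  write_corpus(corpus, paths$corpus, "json")

  profile <- stage("profile", cmi_profile(corpus))
  paths$profile <- file.path(out_dir, "profile.tsv")
  write_tsv(profile$per_sentence, paths$profile)
  paths$profile_summary <- file.path(out_dir, "profile_summary.json")
  jsonlite::write_json(
    list(avg_cmi_en = profile$avg_cmi_en, avg_cmi_zh = profile$avg_cmi_zh,
         cmic = profile$cmic,
         category_counts = as.list(profile$category_counts)),
    paths$profile_summary, auto_unbox = TRUE, digits = NA)

  translator <- resolve_translator(config$translator)
  work <- if (!is.null(translator)) {
    stage("normalize", normalize_corpus(corpus, translator))
  } else corpus

  pred <- if (!is.null(config$llm)) {
    stage("llm-deid", {
      backend <- oracle_llm_backend(
        work,
        noise_rate = config$llm$noise_rate %||% 0.3,
        violation_rate = config$llm$violation_rate %||% 0.2,
        seed = config$seed)
      llm_deid_corpus(backend, prompt_template(), work,
                      k = config$llm$k %||% 3L,
                      min_count = config$llm$min_count %||% 2L)
    })
  } else {
    fitted <- stage("train",
                    fit_tagger(resolve_tagger(config$tagger), work))
    stage("predict", predict_corpus(fitted, work, "TEST"))
  }
  paths$pred <- file.path(out_dir, "pred.json")
  write_corpus(pred, paths$pred, "json")

  gold_test <- corpus_split(work, "TEST")
  report <- stage("evaluate",
                  score(gold_test, pred, criterion = config$criterion,
                        level = config$level))
  rows <- report_rows(report, "ALL")
  strat_reports <- list()
  for (st in config$stratifiers) {
    reps <- stage(paste0("evaluate:", st),
                  score_stratified(gold_test, pred, stratifier = st,
                                   criterion = config$criterion,
                                   level = config$level,
                                   train_vocab = corpus_vocabulary(work)))
    strat_reports[[st]] <- reps
    for (r in reps) rows <- rbind(rows, report_rows(r, paste0(st, ":",
                                                              r$stratum)))
  }
  paths$report <- file.path(out_dir, "report.tsv")
  write_tsv(rows, paths$report)

  ser <- stage("sentence-error-rate",
               sentence_error_rate(gold_test, pred))
  paths$error_rate <- file.path(out_dir, "sentence_error_rate.tsv")
  write_tsv(ser, paths$error_rate)

  invisible(list(corpus = corpus, pred = pred, profile = profile,
                 report = report, stratified = strat_reports,
                 sentence_error_rate = ser, paths = paths))
}
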