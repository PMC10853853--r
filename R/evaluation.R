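#' @name evaluation
#' @title Entity-level evaluation protocol
#' @description
#' Scoring follows the standard de-identification protocol:
#' entity-level true positives are gold/predicted span pairs matched
#' under an exact criterion (identical offsets and fine type) or an
#' approximate criterion (character overlap with identical fine type);
#' precision, recall and F are reported per fine type, pooled (micro) and
#' as the unweighted mean of per-type F over types present in the gold
#' standard (macro).  Coarse-grained mapped scoring credits a match whose
#' fine types differ but share the coarse category.  Additional
#' stratifications: sentence category, CMI bin, and in-vocabulary (IV)
#' versus out-of-vocabulary (OOV) mentions.
NULL

span_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

#' Match predicted spans against gold spans for one document
#'
#' Greedy maximum matching: candidate pairs must agree on (mapped) type
#' and, under `exact`, on both offsets; under `approximate`, overlap by at
#' least one character (or `min_overlap` fraction of the gold span).
#' Pairs are consumed in order of decreasing overlap, ties broken by
#' leftmost gold start; each gold and each predicted span is used at most
#' once.
#'
#' @param gold,pred data.frames with `start`, `end`, `fine_type`.
#' @param criterion "exact" or "approximate".
#' @param min_overlap Minimum overlap as a fraction of the gold span
#'   length (default 0: any overlap counts).
#' @return list(pairs = data.frame(gold, pred) of row indices,
#'   unmatched_gold, unmatched_pred = integer vectors).
#' @export
match_spans <- function(gold, pred, criterion = c("exact", "approximate"),
                        min_overlap = 0) {
  criterion <- match.arg(criterion)
  ng <- nrow(gold); np <- nrow(pred)
  if (!ng || !np) {
    return(list(pairs = data.frame(gold = integer(), pred = integer()),
                unmatched_gold = seq_len(ng),
                unmatched_pred = seq_len(np)))
  }
  cand <- list()
  for (i in seq_len(ng)) {
    for (j in seq_len(np)) {
      if (gold$fine_type[i] != pred$fine_type[j]) next
      if (criterion == "exact") {
        if (gold$start[i] == pred$start[j] && gold$end[i] == pred$end[j]) {
          cand[[length(cand) + 1L]] <- c(i, j, gold$end[i] - gold$start[i])
        }
      } else {
        ov <- span_overlap(gold$start[i], gold$end[i],
                           pred$start[j], pred$end[j])
        need <- max(1L, ceiling(min_overlap *
                                  (gold$end[i] - gold$start[i])))
        if (ov >= need) cand[[length(cand) + 1L]] <- c(i, j, ov)
      }
    }
  }
  pairs <- data.frame(gold = integer(), pred = integer())
  if (length(cand)) {
    m <- do.call(rbind, cand)
    ord <- order(-m[, 3], gold$start[m[, 1]])
    m <- m[ord, , drop = FALSE]
    used_g <- logical(ng); used_p <- logical(np)
    keep <- logical(nrow(m))
    for (r in seq_len(nrow(m))) {
      i <- m[r, 1]; j <- m[r, 2]
      if (!used_g[i] && !used_p[j]) {
        used_g[i] <- TRUE; used_p[j] <- TRUE; keep[r] <- TRUE
      }
    }
    m <- m[keep, , drop = FALSE]
    pairs <- data.frame(gold = m[, 1], pred = m[, 2])
  }
  list(pairs = pairs,
       unmatched_gold = setdiff(seq_len(ng), pairs$gold),
       unmatched_pred = setdiff(seq_len(np), pairs$pred))
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f = f)
}

# collect (doc, stratum) annotation tables and produce an eval_report
score_counts <- function(gold_list, pred_list, criterion, types) {
  tp <- fp <- fn <- stats::setNames(integer(length(types)), types)
  for (d in seq_along(gold_list)) {
    g <- gold_list[[d]]; p <- pred_list[[d]]
    mm <- match_spans(g, p, criterion)
    if (nrow(mm$pairs)) {
      t <- table(factor(g$fine_type[mm$pairs$gold], levels = types))
      tp <- tp + as.integer(t)
    }
    if (length(mm$unmatched_gold)) {
      t <- table(factor(g$fine_type[mm$unmatched_gold], levels = types))
      fn <- fn + as.integer(t)
    }
    if (length(mm$unmatched_pred)) {
      t <- table(factor(p$fine_type[mm$unmatched_pred], levels = types))
      fp <- fp + as.integer(t)
    }
  }
  list(tp = tp, fp = fp, fn = fn)
}

make_report <- function(counts, types, stratum = NA_character_) {
  per_type <- data.frame(fine_type = types,
                         tp = as.integer(counts$tp),
                         fp = as.integer(counts$fp),
                         fn = as.integer(counts$fn),
                         stringsAsFactors = FALSE)
  m <- t(mapply(prf, per_type$tp, per_type$fp, per_type$fn))
  per_type$precision <- m[, "precision"]
  per_type$recall <- m[, "recall"]
  per_type$f <- m[, "f"]
  micro <- prf(sum(per_type$tp), sum(per_type$fp), sum(per_type$fn))
  present <- per_type$tp + per_type$fn > 0  # types with >= 1 gold instance
  macro_f <- if (any(present)) mean(per_type$f[present]) else 0
  structure(
    list(per_type = per_type,
         micro = as.list(micro),
         macro_f = macro_f,
         stratum = stratum),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  hd <- if (is.na(x$stratum)) "" else paste0(" [", x$stratum, "]")
  cat(sprintf("<eval_report>%s micro P=%.3f R=%.3f F=%.3f macro F=%.3f\n",
              hd, x$micro$precision, x$micro$recall, x$micro$f, x$macro_f))
  shown <- x$per_type[x$per_type$tp + x$per_type$fn + x$per_type$fp > 0, ]
  if (nrow(shown)) print(shown, row.names = FALSE, digits = 3)
  invisible(x)
}

doc_pairs <- function(gold_corpus, pred_corpus) {
  gids <- names(gold_corpus)
  pids <- names(pred_corpus)
  common <- intersect(gids, pids)
  missing <- setdiff(pids, gids)
  if (length(missing)) {
    stop("predicted documents missing from gold corpus: ",
         paste(missing, collapse = ", "))
  }
  common
}

#' Score predictions against gold annotations
#'
#' @param gold_corpus Gold `cm_corpus`.
#' @param pred_corpus Predicted `cm_corpus` (documents must exist in the
#'   gold corpus; gold documents absent from `pred_corpus` count as
#'   all-miss only if present in both — scoring runs over the
#'   intersection of `pred_corpus` ids).
#' @param criterion "exact" or "approximate".
#' @param level "fine" scores the 20 fine types; "coarse_mapped" maps both
#'   sides to coarse types first, so a prediction of the wrong fine type
#'   within the right coarse category is a true positive.
#' @param schema PHI schema.
#' @return An `eval_report`.
#' @export
score <- function(gold_corpus, pred_corpus,
                  criterion = c("exact", "approximate"),
                  level = c("fine", "coarse_mapped"),
                  schema = phi_schema()) {
  criterion <- match.arg(criterion)
  level <- match.arg(level)
  ids <- doc_pairs(gold_corpus, pred_corpus)
  map <- function(df) {
    if (level == "coarse_mapped" && nrow(df)) {
      df$fine_type <- coarse_of(df$fine_type, schema)
    }
    df
  }
  types <- if (level == "fine") schema$fine_types else schema$coarse_types
  gold_list <- lapply(ids, function(id) map(gold_corpus[[id]]$annotations))
  pred_list <- lapply(ids, function(id) map(pred_corpus[[id]]$annotations))
  counts <- score_counts(gold_list, pred_list, criterion, types)
  make_report(counts, types)
}

#' Sentence error rate per CMI bin
#'
#' A sentence is wrong if any of its tokens carries an incorrect full
#' BILOU label (position and type).  The rate per bin is the number of
#' wrong sentences divided by the sentences in that CMI range; empty bins
#' are reported as absent.  The bin-size-weighted mean of the rates
#' equals the overall sentence error rate.
#'
#' @param gold_corpus,pred_corpus Gold and predicted corpora over the same
#'   documents.
#' @param edges CMI bin edges, see [bin_by_cmi()].
#' @return data.frame(bin, n, wrong, rate) with attribute `"overall"`.
#' @export
sentence_error_rate <- function(gold_corpus, pred_corpus,
                                edges = default_cmi_edges()) {
  ids <- doc_pairs(gold_corpus, pred_corpus)
  bins <- character(0); wrong <- logical(0)
  for (id in ids) {
    gdoc <- gold_corpus[[id]]; pdoc <- pred_corpus[[id]]
    for (k in seq_along(gdoc$sentences)) {
      s <- gdoc$sentences[[k]]
      gt <- encode_bilou(s$tokens, sentence_annotations(gdoc, s))
      # predicted spans may be snapped; that is expected here, not news
      pt <- suppressWarnings(
        encode_bilou(s$tokens, sentence_annotations(pdoc, s)))
      bins <- c(bins, bin_by_cmi(compute_cmi(s)$value, edges))
      wrong <- c(wrong, !identical(gt, pt))
    }
  }
  if (!length(bins)) {
    out <- data.frame(bin = character(), n = integer(), wrong = integer(),
                      rate = numeric())
    attr(out, "overall") <- NaN
    return(out)
  }
  agg <- stats::aggregate(wrong, by = list(bin = bins),
                          FUN = function(v) c(n = length(v), w = sum(v)))
  out <- data.frame(bin = agg$bin, n = agg$x[, "n"],
                    wrong = agg$x[, "w"],
                    rate = agg$x[, "w"] / agg$x[, "n"],
                    stringsAsFactors = FALSE)
  attr(out, "overall") <- mean(wrong)
  out
}

#' Partition gold mentions into in-vocabulary and out-of-vocabulary
#'
#' A mention is OOV iff it contains at least one token absent from the
#' vocabulary compiled from the training split; an empty vocabulary makes
#' every mention OOV.
#'
#' @param mentions data.frame with columns `mention` and `fine_type`.
#' @param train_vocab Character vector of training token texts.
#' @param schema PHI schema (for per-coarse-type rates).
#' @return list(oov = logical vector aligned with `mentions`, rates =
#'   data.frame(coarse_type, n, oov_rate)).
#' @export
oov_partition <- function(mentions, train_vocab, schema = phi_schema()) {
  oov <- vapply(mentions$mention, function(m) {
    toks <- tokenize_mixed(m)$text
    length(toks) > 0 && any(!toks %in% train_vocab)
  }, logical(1), USE.NAMES = FALSE)
  coarse <- coarse_of(mentions$fine_type, schema)
  rates <- do.call(rbind, lapply(schema$coarse_types, function(ct) {
    sel <- coarse == ct
    data.frame(coarse_type = ct, n = sum(sel),
               oov_rate = if (any(sel)) mean(oov[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(oov = oov, rates = rates)
}

sentence_of_annotation <- function(doc, start) {
  for (k in seq_along(doc$sentences)) {
    s <- doc$sentences[[k]]
    if (start >= s$start && start < s$end) return(k)
  }
  NA_integer_
}

#' Stratified scoring
#'
#' Splits the evaluation by sentence category, CMI bin, or IV/OOV status
#' and scores each stratum separately.  For the sentence-level
#' stratifiers every annotation inherits the stratum of its sentence; for
#' the OOV stratifier each gold or predicted annotation is assigned by
#' its own mention's vocabulary status.  Pooled TP/FP/FN over strata
#' equal the unstratified counts.
#'
#' @inheritParams score
#' @param stratifier One of "sentence_category", "cmi_bin", "oov".
#' @param train_vocab Training vocabulary (required for "oov"; defaults
#'   to the gold corpus's TRAIN split vocabulary).
#' @param edges CMI bin edges for "cmi_bin".
#' @return A named list of `eval_report`s, one per non-empty stratum.
#' @export
score_stratified <- function(gold_corpus, pred_corpus,
                             stratifier = c("sentence_category", "cmi_bin",
                                            "oov"),
                             criterion = c("exact", "approximate"),
                             level = c("fine", "coarse_mapped"),
                             train_vocab = NULL,
                             edges = default_cmi_edges(),
                             schema = phi_schema()) {
  stratifier <- match.arg(stratifier)
  criterion <- match.arg(criterion)
  level <- match.arg(level)
  ids <- doc_pairs(gold_corpus, pred_corpus)
  if (stratifier == "oov" && is.null(train_vocab)) {
    train_vocab <- corpus_vocabulary(gold_corpus, "TRAIN")
  }
  types <- if (level == "fine") schema$fine_types else schema$coarse_types
  map <- function(df) {
    if (level == "coarse_mapped" && nrow(df)) {
      df$fine_type <- coarse_of(df$fine_type, schema)
    }
    df
  }
  ann_strata <- function(doc, df) {
    if (!nrow(df)) return(character(0))
    if (stratifier == "oov") {
      ifelse(oov_partition(df, train_vocab, schema)$oov, "OOV", "IV")
    } else {
      vapply(df$start, function(st) {
        k <- sentence_of_annotation(doc, st)
        s <- doc$sentences[[k]]
        if (stratifier == "sentence_category") s$category
        else bin_by_cmi(compute_cmi(s)$value, edges)
      }, character(1))
    }
  }
  # per stratum, collect per-document gold/pred tables
  strata <- list()
  for (id in ids) {
    gdoc <- gold_corpus[[id]]; pdoc <- pred_corpus[[id]]
    g <- gdoc$annotations; p <- pdoc$annotations
    gs <- ann_strata(gdoc, g); ps <- ann_strata(gdoc, p)
    for (st in union(gs, ps)) {
      cur <- strata[[st]] %||% list(gold = list(), pred = list())
      cur$gold[[length(cur$gold) + 1L]] <-
        map(g[gs == st, , drop = FALSE])
      cur$pred[[length(cur$pred) + 1L]] <-
        map(p[ps == st, , drop = FALSE])
      strata[[st]] <- cur
    }
  }
  out <- lapply(names(strata), function(st) {
    counts <- score_counts(strata[[st]]$gold, strata[[st]]$pred,
                           criterion, types)
    make_report(counts, types, stratum = st)
  })
  stats::setNames(out, names(strata))
}

#' PHI distribution by sentence category
#'
#' The distribution-profile table: counts of annotations per (fine type,
#' sentence category, split), with row and column totals available via
#' `margin.table()`.
#'
#' @param corpus A `cm_corpus`.
#' @param schema PHI schema.
#' @return A 3-way table fine type x category x split.
#' @export
phi_distribution <- function(corpus, schema = phi_schema()) {
  ft <- character(0); cat_ <- character(0); split <- character(0)
  for (doc in corpus) {
    ann <- doc$annotations
    if (!nrow(ann)) next
    cats <- vapply(ann$start, function(st) {
      doc$sentences[[sentence_of_annotation(doc, st)]]$category
    }, character(1))
    ft <- c(ft, ann$fine_type)
    cat_ <- c(cat_, cats)
    split <- c(split, rep(doc$split, nrow(ann)))
  }
  table(
    fine_type = factor(ft, levels = schema$fine_types),
    category = factor(cat_, levels = sentence_categories()),
    split = factor(split, levels = c("TRAIN", "TEST"))
  )
}
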