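#' @name bilou
#' @title BILOU span codec
#' @description
#' PHI recognition is treated as sequential tagging under the BILOU
#' schema: tokens of a multi-token PHI are labeled B (beginning),
#' I (within) and L (last); single-token PHI are U; non-PHI tokens are O.
#' Typed labels take the form `"B-Hospital"`, `"U-Date"`, etc.
#' `encode_bilou()` and `decode_bilou()` convert between character-offset
#' spans and token-aligned label sequences; `repair_bilou()` restores
#' grammar validity of arbitrary label sequences.
NULL

split_label <- function(labels) {
  pos <- ifelse(labels == "O", "O", substr(labels, 1, 1))
  type <- ifelse(labels == "O", NA_character_, substring(labels, 3))
  list(pos = pos, type = type)
}

#' Encode character spans as a BILOU label sequence
#'
#' Spans whose boundaries fall inside a token are expanded outward to the
#' nearest token boundaries (never truncated): for de-identification it is
#' safer to over-mask than to leave a fragment of PHI behind.  Snapped
#' spans are reported in the `"snapped"` attribute and via a warning.
#'
#' @param tokens Token data.frame (see [tokenize_mixed()]), offsets relative
#'   to the same text as `spans`.
#' @param spans data.frame with columns `start`, `end` (0-based half-open)
#'   and `fine_type`; spans must not overlap.
#' @return Character vector of labels, one per token.
#' @examples
#' tok <- tokenize_mixed("seen at Mercy Hospital")
#' encode_bilou(tok, data.frame(start = 8, end = 22, fine_type = "Hospital"))
#' @export
encode_bilou <- function(tokens, spans) {
  labels <- rep("O", nrow(tokens))
  if (is.null(spans) || nrow(spans) == 0) return(labels)
  spans <- spans[order(spans$start), , drop = FALSE]
  if (nrow(spans) > 1 &&
      any(spans$start[-1] < spans$end[-nrow(spans)])) {
    stop("spans overlap; annotations within one sentence must be disjoint")
  }
  snapped <- character(0)
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]
    covered <- which(tokens$end > s & tokens$start < e)
    if (!length(covered)) next
    exp_s <- tokens$start[covered[1]]
    exp_e <- tokens$end[covered[length(covered)]]
    if (exp_s != s || exp_e != e) {
      snapped <- c(snapped, sprintf("[%d,%d)->[%d,%d)", s, e, exp_s, exp_e))
    }
    ft <- spans$fine_type[i]
    if (length(covered) == 1L) {
      labels[covered] <- paste0("U-", ft)
    } else {
      labels[covered[1]] <- paste0("B-", ft)
      labels[covered[length(covered)]] <- paste0("L-", ft)
      if (length(covered) > 2L) {
        labels[covered[-c(1, length(covered))]] <- paste0("I-", ft)
      }
    }
  }
  if (length(snapped)) {
    warning("span boundaries snapped outward to token boundaries: ",
            paste(snapped, collapse = "; "))
    attr(labels, "snapped") <- snapped
  }
  labels
}

#' Decode a BILOU label sequence into character spans
#'
#' Invalid sequences are repaired with [repair_bilou()] first, so
#' `decode_bilou(tokens, encode_bilou(tokens, spans))` reproduces
#' token-aligned `spans` exactly.
#'
#' @inheritParams encode_bilou
#' @param labels Character vector of labels aligned with `tokens`.
#' @return data.frame with columns `start`, `end`, `fine_type`.
#' @export
decode_bilou <- function(tokens, labels) {
  if (length(labels) != nrow(tokens)) {
    stop("label sequence length (", length(labels),
         ") does not match token count (", nrow(tokens), ")")
  }
  labels <- repair_bilou(labels)
  lab <- split_label(labels)
  out <- list()
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    if (lab$pos[i] == "U") {
      out[[length(out) + 1L]] <- c(tokens$start[i], tokens$end[i], i, i)
      i <- i + 1L
    } else if (lab$pos[i] == "B") {
      j <- i
      while (j < n && lab$pos[j + 1L] %in% c("I", "L") &&
             identical(lab$type[j + 1L], lab$type[i])) {
        j <- j + 1L
        if (lab$pos[j] == "L") break
      }
      out[[length(out) + 1L]] <- c(tokens$start[i], tokens$end[j], i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      fine_type = character(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             fine_type = lab$type[m[, 3]], stringsAsFactors = FALSE)
}

#' Repair an invalid BILOU label sequence
#'
#' Per-token taggers (e.g. the dictionary baseline) ignore the BILOU
#' grammar.  Repair re-encodes each maximal run of same-type non-O labels
#' as U (run length 1) or B..I..L (length >= 2); a type change splits runs.
#' The operation is idempotent and never changes the \emph{type} of a
#' non-O token, only its positional prefix.
#'
#' @param labels Character vector of (possibly invalid) labels.
#' @return A valid BILOU label vector of the same length.
#' Within a maximal same-type run, adjacent \emph{valid} entities are kept
#' separate: the run is additionally split wherever a label in `{L, U}`
#' is followed by one in `{B, U}`, so valid sequences pass through
#' unchanged (e.g. `U-City, B-City, L-City` stays two entities).
#'
#' @examples
#' repair_bilou(c("I-Date"))              # "U-Date"
#' repair_bilou(c("B-City", "B-City"))    # "B-City" "L-City"
#' @export
repair_bilou <- function(labels) {
  n <- length(labels)
  if (!n) return(labels)
  lab <- split_label(labels)
  out <- labels
  emit <- function(i, j, ft) {
    if (j == i) {
      out[i] <<- paste0("U-", ft)
    } else {
      out[i] <<- paste0("B-", ft)
      out[j] <<- paste0("L-", ft)
      if (j - i > 1L) out[(i + 1L):(j - 1L)] <<- paste0("I-", ft)
    }
  }
  i <- 1L
  while (i <= n) {
    if (lab$pos[i] == "O") { i <- i + 1L; next }
    j <- i
    while (j < n && lab$pos[j + 1L] != "O" &&
           identical(lab$type[j + 1L], lab$type[i]) &&
           !(lab$pos[j] %in% c("L", "U") &&
             lab$pos[j + 1L] %in% c("B", "U"))) {
      j <- j + 1L
    }
    emit(i, j, lab$type[i])
    i <- j + 1L
  }
  out
}

#' Convert between BILOU and BIO label sequences
#'
#' BILOU is the canonical internal scheme; BIO is supported for
#' interchange.  The conversion is lossless: `bio_to_bilou(bilou_to_bio(x))`
#' equals `x` for valid sequences.
#'
#' @param labels A valid label vector in the source scheme.
#' @return A label vector in the target scheme.
#' @export
bilou_to_bio <- function(labels) {
  pos <- substr(labels, 1, 1)
  out <- labels
  out[pos == "U"] <- sub("^U-", "B-", labels[pos == "U"])
  out[pos == "L"] <- sub("^L-", "I-", labels[pos == "L"])
  out
}

#' @rdname bilou_to_bio
#' @export
bio_to_bilou <- function(labels) {
  n <- length(labels)
  if (!n) return(labels)
  lab <- split_label(labels)
  out <- labels
  i <- 1L
  while (i <= n) {
    if (lab$pos[i] == "O") { i <- i + 1L; next }
    # a BIO entity starts here (B, or stray I treated as a start)
    j <- i
    while (j < n && lab$pos[j + 1L] == "I" &&
           identical(lab$type[j + 1L], lab$type[i])) j <- j + 1L
    ft <- lab$type[i]
    if (j == i) {
      out[i] <- paste0("U-", ft)
    } else {
      out[i] <- paste0("B-", ft)
      out[j] <- paste0("L-", ft)
      if (j - i > 1L) out[(i + 1L):(j - 1L)] <- paste0("I-", ft)
    }
    i <- j + 1L
  }
  out
}
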