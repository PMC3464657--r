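# Evaluation: per-value precision/recall/F, macro and micro averages,
# majority baseline.  All averaging uses unrounded intermediates; percentages
# are rounded half-up to one decimal only at reporting time.

#' Round half-up (reporting convention for percentages)
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return `x` rounded with halves away from zero.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-value precision, recall and F-score
#'
#' @param gold,pred aligned gold and predicted label vectors over the same
#'   events.
#' @param values the dimension's legal values (rows are reported for all of
#'   them, including zero-support values, as `0/0/0`).
#' @return Data frame with columns `value`, `gold_n`, `pred_n`, `tp`, `P`,
#'   `R`, `F` (percentages, unrounded).
#' @export
prf <- function(gold, pred, values = sort(unique(c(gold, pred)))) {
  gold <- as.character(gold); pred <- as.character(pred)
  if (length(gold) != length(pred)) stop("gold/pred length mismatch")
  rows <- lapply(values, function(v) {
    gn <- sum(gold == v); pn <- sum(pred == v); tp <- sum(gold == v & pred == v)
    P <- if (pn > 0) 100 * tp / pn else 0
    R <- if (gn > 0) 100 * tp / gn else 0
    F <- if (P + R > 0) 2 * P * R / (P + R) else 0
    data.frame(value = v, gold_n = gn, pred_n = pn, tp = tp, P = P, R = R, F = F,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Macro and micro averages of per-value rows
#'
#' Macro averages are unweighted means of per-value P, R and F over all
#' legal values (zero-support rows included).  Micro averages pool the
#' counts; with exactly one gold and one predicted value per event, micro
#' P = R = F = accuracy.
#'
#' @param rows output of [prf()] covering all legal values of a dimension.
#' @return List with numeric vectors `macro` and `micro`, each
#'   `c(P =, R =, F =)` (percentages, unrounded).
#' @export
macro_micro <- function(rows) {
  macro <- c(P = mean(rows$P), R = mean(rows$R), F = mean(rows$F))
  tp <- sum(rows$tp); gn <- sum(rows$gold_n); pn <- sum(rows$pred_n)
  P <- if (pn > 0) 100 * tp / pn else 0
  R <- if (gn > 0) 100 * tp / gn else 0
  F <- if (P + R > 0) 2 * P * R / (P + R) else 0
  list(macro = macro, micro = c(P = P, R = R, F = F))
}

#' Full evaluation table for one dimension
#'
#' @inheritParams prf
#' @param dimension dimension name (for printing).
#' @return An `mk_eval` list: `dimension`, `rows` (per-value [prf()] rows),
#'   `macro`, `micro`, `n`.
#' @export
eval_dimension <- function(gold, pred, values, dimension = "label") {
  rows <- prf(gold, pred, values)
  mm <- macro_micro(rows)
  structure(list(dimension = dimension, rows = rows, macro = mm$macro,
                 micro = mm$micro, n = length(gold)),
            class = "mk_eval")
}

#' @exportS3Method base::print
print.mk_eval <- function(x, ...) {
  fmt <- function(r, p, f) sprintf("%.1f / %.1f / %.1f", round_half_up(r),
                                   round_half_up(p), round_half_up(f))
  cat(sprintf("%s (n = %d)\n", x$dimension, x$n))
  for (k in seq_len(nrow(x$rows))) {
    r <- x$rows[k, ]
    cat(sprintf("  %-14s %6d  R/P/F %s\n", r$value, r$gold_n,
                fmt(r$R, r$P, r$F)))
  }
  cat(sprintf("  %-14s %6s  R/P/F %s\n", "Macro Average", "",
              fmt(x$macro[["R"]], x$macro[["P"]], x$macro[["F"]])))
  cat(sprintf("  %-14s %6s  R/P/F %s\n", "Micro Average", "",
              fmt(x$micro[["R"]], x$micro[["P"]], x$micro[["F"]])))
  invisible(x)
}

#' Majority-value baseline
#'
#' Predicts the most frequent gold value for every event and evaluates that
#' prediction (ties break towards the earlier value in `values`).
#'
#' @inheritParams eval_dimension
#' @return An `mk_eval` table.
#' @export
majority_baseline <- function(gold, values, dimension = "label") {
  gold <- as.character(gold)
  counts <- vapply(values, function(v) sum(gold == v), integer(1))
  maj <- values[which.max(counts)]
  eval_dimension(gold, rep(maj, length(gold)), values, dimension)
}

# gold labels of a corpus, one row per usable event, aligned across dims
.corpus_gold <- function(docs) {
  evs <- .corpus_events(docs, require_mk = TRUE)
  doc_index <- setNames(docs, vapply(docs, `[[`, character(1), "doc_id"))
  labs <- lapply(mk_dimensions(), function(d) {
    vapply(evs, function(e) doc_index[[e$doc]]$mk[[e$event]][[d]], character(1))
  })
  names(labs) <- mk_dimensions()
  list(events = evs, labels = labs)
}

#' Evaluate predicted meta-knowledge against gold, per dimension
#'
#' Events are aligned by (document, event id); events present in only one of
#' the corpora are an error (the protocol assumes gold event alignment).
#'
#' @param gold_docs,pred_docs named lists of `mk_document`s carrying gold and
#'   predicted meta-knowledge respectively.
#' @return Named list of `mk_eval` tables, one per dimension.
#' @export
evaluate_corpus <- function(gold_docs, pred_docs) {
  g <- .corpus_gold(gold_docs)
  pred_index <- setNames(pred_docs, vapply(pred_docs, `[[`, character(1), "doc_id"))
  out <- list()
  for (d in mk_dimensions()) {
    pred <- vapply(g$events, function(e) {
      rec <- pred_index[[e$doc]]$mk[[e$event]]
      if (is.null(rec)) stop(sprintf("no prediction for event %s in %s", e$event, e$doc))
      rec[[d]]
    }, character(1))
    out[[d]] <- eval_dimension(g$labels[[d]], pred, mk_scheme()[[d]], d)
  }
  out
}

#' Majority baseline over a gold corpus, per dimension
#' @param gold_docs named list of `mk_document`s with gold meta-knowledge.
#' @return Named list of `mk_eval` tables, one per dimension.
#' @export
corpus_majority_baseline <- function(gold_docs) {
  g <- .corpus_gold(gold_docs)
  out <- list()
  for (d in mk_dimensions()) {
    out[[d]] <- majority_baseline(g$labels[[d]], mk_scheme()[[d]], d)
  }
  out
}
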