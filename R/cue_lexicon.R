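# Cue (clue) word lexicons
# ------------------------
# A cue lexicon maps lemmatised words (possibly multi-word, space-joined) to
# (dimension, value) pairs, scored by pointwise mutual information between
# the word's occurrence as an annotated cue mention and the meta-knowledge
# value of co-occurring events.  Only entries with PMI >= tau survive.

#' Pointwise mutual information of a (word, value) pair
#'
#' `PMI = log( (joint/total) / ((word/total) * (value/total)) )` in the
#' configured base.  Counting is over events: `joint` is the number of events
#' that both carry the value and co-occur with the word in their sentence.
#'
#' @param joint events co-occurring with the word and carrying the value.
#' @param word events co-occurring with the word.
#' @param value events carrying the value.
#' @param total total number of events.
#' @param base logarithm base (default 2; any base only rescales scores).
#' @return PMI score; `-Inf` when `joint` is 0 (such entries never pass the
#'   threshold).
#' @export
#' @examples
#' compute_pmi(40, 50, 100, 1000)  # log2(0.04 / (0.05 * 0.1)) = 3
compute_pmi <- function(joint, word, value, total, base = 2) {
  stopifnot(total > 0, joint <= word, joint <= value, word <= total, value <= total)
  if (joint == 0) return(-Inf)
  log((joint / total) / ((word / total) * (value / total)), base = base)
}

.new_cue_lexicon <- function(entries, tau, base) {
  entries <- entries[order(match(entries$dimension, mk_dimensions()),
                           -entries$pmi, entries$value, entries$word), , drop = FALSE]
  rownames(entries) <- NULL
  structure(entries, tau = tau, base = base, class = c("cue_lexicon", "data.frame"))
}

#' @exportS3Method base::print
print.cue_lexicon <- function(x, ...) {
  cat(sprintf("<cue_lexicon: %d entries, tau = %g, log base = %g>\n",
              nrow(x), attr(x, "tau"), attr(x, "base")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

# lemma key of a text-bound: space-joined lower-cased lemmas of covered tokens
.cue_word_of_tb <- function(doc, tb) {
  k <- .sentence_of_span(doc, tb$span)
  if (is.na(k)) return(NA_character_)
  tok <- doc$sentences[[k]]$tokens
  covered <- which(tok$start < tb$span[2L] & tok$end > tb$span[1L])
  if (!length(covered)) return(NA_character_)
  paste(tolower(tok$lemma[covered]), collapse = " ")
}

# events usable for lexicon induction / training: trigger resolvable to a
# parsed sentence and a gold mk record present (if require_mk)
.corpus_events <- function(docs, require_mk = TRUE) {
  out <- list()
  for (doc in docs) {
    for (ev in doc$events) {
      if (is.na(ev$trigger)) next
      if (require_mk && is.null(doc$mk[[ev$id]])) next
      k <- .sentence_of_span(doc, doc$textbounds[[ev$trigger]]$span)
      if (is.na(k)) next
      out[[length(out) + 1L]] <- list(doc = doc$doc_id, event = ev$id, sentence = k)
    }
  }
  out
}

#' Induce a cue lexicon from an annotated corpus
#'
#' Collects every word annotated as a cue mention in the training corpus
#' (plus, optionally, words from an external lexicon), counts event/word
#' co-occurrences per (word, dimension, value) triple, scores each triple by
#' [compute_pmi()] and keeps those with PMI at or above the threshold.  An
#' event co-occurs with a word when the word is a cue mention in the event's
#' sentence; external-lexicon words without corpus cue annotation are counted
#' by lemma matching instead.
#'
#' @param docs named list of `mk_document`s with parses, gold meta-knowledge
#'   and cue text-bounds (kind `<Dimension>-cue`).
#' @param tau PMI threshold (default -1.5, interpreted in the configured log
#'   base).
#' @param external optional data frame (`word`, `dimension`, `value`) of
#'   externally supplied candidate cues.
#' @param base PMI logarithm base (default 2).
#' @return A `cue_lexicon`: data frame (`word`, `dimension`, `value`, `pmi`)
#'   sorted by dimension then descending PMI.
#' @export
build_cue_lexicon <- function(docs, tau = -1.5, external = NULL, base = 2) {
  evs <- .corpus_events(docs, require_mk = TRUE)
  total <- length(evs)
  # per (doc, sentence) -> set of annotated cue words
  sent_cues <- list()
  any_cue <- FALSE
  for (doc in docs) {
    for (tb in doc$textbounds) {
      if (!grepl("-cue$", tb$kind)) next
      any_cue <- TRUE
      w <- .cue_word_of_tb(doc, tb)
      if (is.na(w)) next
      k <- .sentence_of_span(doc, tb$span)
      key <- paste0(doc$doc_id, "#", k)
      sent_cues[[key]] <- unique(c(sent_cues[[key]], w))
    }
  }
  empty <- .new_cue_lexicon(data.frame(word = character(), dimension = character(),
                                       value = character(), pmi = numeric(),
                                       stringsAsFactors = FALSE), tau, base)
  if (!any_cue && is.null(external)) {
    warning("corpus has no cue annotations; returning an empty lexicon")
    return(empty)
  }
  if (total == 0L) {
    warning("no usable events (parsed sentence + gold meta-knowledge); empty lexicon")
    return(empty)
  }
  corpus_words <- sort(unique(unlist(sent_cues, use.names = FALSE)))
  ext_words <- character()
  if (!is.null(external)) {
    stopifnot(all(c("word", "dimension", "value") %in% names(external)))
    ext_words <- setdiff(tolower(external$word), corpus_words)
  }
  doc_index <- setNames(docs, vapply(docs, `[[`, character(1), "doc_id"))

  # word -> logical over events: co-occurrence
  occ <- function(word, via_annotation) {
    vapply(evs, function(e) {
      if (via_annotation) {
        word %in% sent_cues[[paste0(e$doc, "#", e$sentence)]]
      } else {
        lem <- tolower(doc_index[[e$doc]]$sentences[[e$sentence]]$tokens$lemma)
        parts <- strsplit(word, " ", fixed = TRUE)[[1L]]
        if (length(parts) == 1L) parts %in% lem else
          grepl(paste0(" ", word, " "), paste0(" ", paste(lem, collapse = " "), " "),
                fixed = TRUE)
      }
    }, logical(1))
  }
  gold <- lapply(evs, function(e) doc_index[[e$doc]]$mk[[e$event]])

  rows <- list()
  score_word <- function(word, via_annotation) {
    w_occ <- occ(word, via_annotation)
    w_cnt <- sum(w_occ)
    if (w_cnt == 0L) return(NULL)
    for (d in mk_dimensions()) {
      vals <- vapply(gold, function(m) m[[d]], character(1))
      for (v in mk_scheme()[[d]]) {
        v_cnt <- sum(vals == v)
        if (v_cnt == 0L) next
        joint <- sum(w_occ & vals == v)
        pmi <- compute_pmi(joint, w_cnt, v_cnt, total, base = base)
        if (is.finite(pmi) && pmi >= tau) {
          rows[[length(rows) + 1L]] <<- data.frame(word = word, dimension = d,
                                                   value = v, pmi = pmi,
                                                   stringsAsFactors = FALSE)
        }
      }
    }
  }
  for (w in corpus_words) score_word(w, TRUE)
  for (w in ext_words) score_word(w, FALSE)
  if (!length(rows)) return(empty)
  .new_cue_lexicon(do.call(rbind, rows), tau, base)
}

#' Write a cue lexicon to a tab-separated file
#' @param lexicon a `cue_lexicon`.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_cue_lexicon <- function(lexicon, file) {
  hdr <- sprintf("# tau=%s base=%s", format(attr(lexicon, "tau")),
                 format(attr(lexicon, "base")))
  body <- sprintf("%s\t%s\t%s\t%s", lexicon$word, lexicon$dimension,
                  lexicon$value, formatC(lexicon$pmi, digits = 17, format = "g"))
  writeLines(c(hdr, body), file, useBytes = TRUE)
  invisible(file)
}

#' Read a cue lexicon written by [write_cue_lexicon()]
#' @param file path to the lexicon file.
#' @return A `cue_lexicon`.
#' @export
read_cue_lexicon <- function(file) {
  lines <- readLines(file, encoding = "UTF-8")
  tau <- -1.5; base <- 2
  if (length(lines) && startsWith(lines[1L], "#")) {
    m <- regmatches(lines[1L], regexec("tau=([^ ]+) base=([^ ]+)", lines[1L]))[[1L]]
    if (length(m) == 3L) { tau <- as.numeric(m[2L]); base <- as.numeric(m[3L]) }
    lines <- lines[-1L]
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(.new_cue_lexicon(data.frame(word = character(), dimension = character(),
                                       value = character(), pmi = numeric(),
                                       stringsAsFactors = FALSE), tau, base))
  }
  mat <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  .new_cue_lexicon(data.frame(word = mat[, 1L], dimension = mat[, 2L],
                              value = mat[, 3L], pmi = as.numeric(mat[, 4L]),
                              stringsAsFactors = FALSE), tau, base)
}

# stable checksum of a lexicon, used to guard model/lexicon compatibility
.lexicon_checksum <- function(lexicon) {
  key <- paste(lexicon$word, lexicon$dimension, lexicon$value,
               formatC(lexicon$pmi, digits = 10, format = "g"),
               sep = "\t", collapse = "\n")
  .fnv1a_hash(key, 30L)
}

#' Match lexicon cues in a parsed sentence
#'
#' Matching is on lower-cased lemmas; multi-word cues are matched as
#' contiguous lemma sequences, longest match first (the scan resumes after a
#' multi-word match).
#'
#' @param sentence a sentence element of an `mk_document` (tokens with
#'   lemmas).
#' @param lexicon a `cue_lexicon`.
#' @return List of cue mentions: each a list with `span` (`c(start, end)`
#'   character offsets), `first_token`/`last_token` (row indices), `word`
#'   (matched lemma key) and `entries` (the matching lexicon rows).
#' @export
match_cues <- function(sentence, lexicon) {
  tok <- sentence$tokens
  if (!nrow(lexicon)) return(list())
  lem <- tolower(tok$lemma)
  words <- unique(lexicon$word)
  by_len <- split(words, lengths(strsplit(words, " ", fixed = TRUE)))
  max_len <- max(as.integer(names(by_len)))
  mentions <- list()
  i <- 1L
  n <- length(lem)
  while (i <= n) {
    matched_len <- 0L
    for (L in seq(min(max_len, n - i + 1L), 1L)) {
      key <- paste(lem[i:(i + L - 1L)], collapse = " ")
      if (key %in% words) {
        entries <- lexicon[lexicon$word == key, , drop = FALSE]
        mentions[[length(mentions) + 1L]] <- list(
          span = c(tok$start[i], tok$end[i + L - 1L]),
          first_token = i, last_token = i + L - 1L,
          word = key, entries = as.data.frame(entries))
        matched_len <- L
        break
      }
    }
    i <- i + max(1L, matched_len)
  }
  mentions
}

#' Detect citation strings in a sentence
#'
#' A citation is a bracketed number (e.g. `[108]`) or a parenthesised
#' sequence ending in four digits (e.g. `(Smith et al., 1998)`).
#'
#' @param text raw sentence text.
#' @return List with `flag` (logical) and `spans`, a two-column matrix of
#'   0-based half-open offsets of each citation within `text`.
#' @export
#' @examples
#' detect_citations("It was shown [108].")$flag
detect_citations <- function(text) {
  pat <- "\\[\\s*\\d+(\\s*[,;–-]\\s*\\d+)*\\s*\\]|\\([^()]*\\d{4}\\s*\\)"
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(list(flag = FALSE, spans = matrix(integer(), ncol = 2L,
                                             dimnames = list(NULL, c("start", "end")))))
  }
  starts <- as.integer(m) - 1L
  ends <- starts + attr(m, "match.length")
  list(flag = TRUE, spans = cbind(start = starts, end = ends))
}
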