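# Standoff annotation dialect
# ---------------------------
# A document is stored as three text files sharing a basename:
#   <id>.txt    raw UTF-8 text
#   <id>.a1     entity text-bounds        T<k> TAB Kind start end[;start end]* TAB surface
#   <id>.a2     trigger and cue text-bounds (same line format as .a1),
#               events                    E<k> TAB Type:Ttrig Role:Ref ...
#               meta-knowledge attributes A<k> TAB Dimension EventId Value
#               cue<->event links         #<k> TAB CueLink EventId Dimension TbId
# Offsets are 0-based, half-open, indexing the raw text.  Discontinuous
# text-bounds list their fragments separated by ';'; the surface column then
# holds the fragment slices joined by a single space.
# Parses live in <id>.conll: one block per (sentence, parser), a comment line
#   # sent <index> <start> <end> <parser>
# followed by rows INDEX TAB FORM TAB LEMMA TAB POS TAB HEAD TAB DEPREL,
# blocks separated by blank lines.  Token character offsets are recovered by
# aligning FORM sequences against the sentence text.

new_textbound <- function(id, kind, fragments, surface, layer = "a2") {
  frags <- lapply(fragments, function(f) as.integer(f))
  span <- resolve_discontinuous_span(frags)
  structure(list(id = id, kind = kind, fragments = frags, span = span,
                 surface = surface, layer = layer),
            class = "mk_textbound")
}

new_event <- function(id, type, trigger, args) {
  structure(list(id = id, type = type, trigger = trigger, args = args),
            class = "mk_event")
}

#' Resolve a discontinuous annotation span
#'
#' Discontinuous text-bound fragments are replaced by the smallest continuous
#' span that covers all of them: `(min start, max end)`.
#'
#' @param fragments non-empty list of `c(start, end)` integer pairs
#'   (0-based, half-open).
#' @return Integer vector `c(start, end)`.
#' @export
#' @examples
#' resolve_discontinuous_span(list(c(10L, 15L), c(20L, 26L)))
resolve_discontinuous_span <- function(fragments) {
  if (length(fragments) == 0L) stop("empty fragment list")
  starts <- vapply(fragments, function(f) as.integer(f[1L]), integer(1))
  ends <- vapply(fragments, function(f) as.integer(f[2L]), integer(1))
  if (any(starts >= ends)) stop("fragment with start >= end")
  c(min(starts), max(ends))
}

.slice <- function(text, start, end) substr(text, start + 1L, end)

.tb_surface <- function(text, fragments) {
  paste(vapply(fragments, function(f) .slice(text, f[1L], f[2L]), character(1)),
        collapse = " ")
}

.parse_tb_line <- function(line, text, layer, file) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(parts) != 3L) stop(sprintf("malformed text-bound line in %s: %s", file, line))
  head_parts <- strsplit(parts[2L], " ", fixed = TRUE)[[1L]]
  kind <- head_parts[1L]
  offs <- strsplit(paste(head_parts[-1L], collapse = " "), ";", fixed = TRUE)[[1L]]
  fragments <- lapply(offs, function(o) as.integer(strsplit(trimws(o), " ")[[1L]]))
  for (f in fragments) {
    if (length(f) != 2L || anyNA(f)) {
      stop(sprintf("malformed offsets in %s: %s", file, line))
    }
    if (f[1L] < 0L || f[2L] > nchar(text) || f[1L] >= f[2L]) {
      stop(sprintf("offset out of range in %s: %s", file, line))
    }
  }
  expected <- .tb_surface(text, fragments)
  if (!identical(expected, parts[3L])) {
    stop(sprintf("surface mismatch in %s at %s: annotation '%s' vs text '%s'",
                 file, parts[1L], parts[3L], expected))
  }
  new_textbound(parts[1L], kind, fragments, parts[3L], layer)
}

.parse_event_line <- function(line, file) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop(sprintf("malformed event line in %s: %s", file, line))
  toks <- strsplit(parts[2L], " ", fixed = TRUE)[[1L]]
  toks <- toks[nzchar(toks)]
  first <- strsplit(toks[1L], ":", fixed = TRUE)[[1L]]
  type <- first[1L]
  trigger <- if (length(first) >= 2L && nzchar(first[2L])) first[2L] else NA_character_
  args <- list()
  for (tk in toks[-1L]) {
    kv <- strsplit(tk, ":", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop(sprintf("malformed argument '%s' in %s", tk, file))
    args[[length(args) + 1L]] <- list(role = kv[1L], ref = kv[2L])
  }
  new_event(parts[1L], type, trigger, args)
}

.check_event_refs <- function(events, textbounds, file = "<standoff>") {
  ids <- c(names(textbounds), names(events))
  for (ev in events) {
    if (!is.na(ev$trigger) && !ev$trigger %in% names(textbounds)) {
      stop(sprintf("unresolved trigger reference %s in event %s (%s)",
                   ev$trigger, ev$id, file))
    }
    for (a in ev$args) {
      if (!a$ref %in% ids) {
        stop(sprintf("unresolved reference %s in event %s (%s)", a$ref, ev$id, file))
      }
    }
  }
  # acyclicity of event->event argument references (DFS with colouring)
  colour <- setNames(rep(0L, length(events)), names(events))
  visit <- function(id) {
    if (colour[[id]] == 1L) stop(sprintf("cyclic event nesting at %s (%s)", id, file))
    if (colour[[id]] == 2L) return(invisible())
    colour[[id]] <<- 1L
    for (a in events[[id]]$args) {
      if (startsWith(a$ref, "E")) visit(a$ref)
    }
    colour[[id]] <<- 2L
  }
  for (id in names(events)) visit(id)
  invisible(TRUE)
}

#' Read a standoff-annotated document
#'
#' Reads the raw text, the entity file (`.a1`) and the event file (`.a2`) of
#' one document, resolves all references and verifies every annotated surface
#' string against the text offsets.
#'
#' @param text_file path to the `.txt` file.
#' @param a1_file path to the `.a1` entity file.
#' @param a2_file path to the `.a2` event file (triggers, cue text-bounds,
#'   events, meta-knowledge attributes, cue links).
#' @param doc_id document identifier; defaults to the text file basename.
#' @return An `mk_document`: a list with elements `doc_id`, `text`,
#'   `textbounds`, `events`, `mk` (per-event [mk_record()]s), `cue_links`
#'   (data frame `event_id`/`dimension`/`tb_id`) and `sentences` (empty until
#'   [read_parse()] is applied).
#' @seealso [write_standoff()], [read_parse()], [read_corpus()]
#' @export
read_standoff <- function(text_file, a1_file, a2_file,
                          doc_id = sub("\\.txt$", "", basename(text_file))) {
  text <- readChar(text_file, file.size(text_file), useBytes = FALSE)
  Encoding(text) <- "UTF-8"
  textbounds <- list()
  events <- list()
  mk <- list()
  cue_links <- data.frame(event_id = character(), dimension = character(),
                          tb_id = character(), stringsAsFactors = FALSE)

  a1_lines <- if (file.exists(a1_file)) readLines(a1_file, encoding = "UTF-8") else character()
  for (line in a1_lines[nzchar(a1_lines)]) {
    tb <- .parse_tb_line(line, text, "a1", a1_file)
    if (tb$id %in% names(textbounds)) stop(sprintf("duplicate id %s in %s", tb$id, a1_file))
    textbounds[[tb$id]] <- tb
  }
  a2_lines <- if (file.exists(a2_file)) readLines(a2_file, encoding = "UTF-8") else character()
  for (line in a2_lines[nzchar(a2_lines)]) {
    tag <- substr(line, 1L, 1L)
    if (tag == "T") {
      tb <- .parse_tb_line(line, text, "a2", a2_file)
      if (tb$id %in% names(textbounds)) stop(sprintf("duplicate id %s in %s", tb$id, a2_file))
      textbounds[[tb$id]] <- tb
    } else if (tag == "E") {
      ev <- .parse_event_line(line, a2_file)
      events[[ev$id]] <- ev
    } else if (tag == "A") {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
      fields <- strsplit(parts[2L], " ", fixed = TRUE)[[1L]]
      if (length(fields) != 3L) stop(sprintf("malformed attribute line in %s: %s", a2_file, line))
      dim <- fields[1L]; ev_id <- fields[2L]; value <- fields[3L]
      if (!dim %in% mk_dimensions()) stop(sprintf("unknown dimension '%s' in %s", dim, a2_file))
      if (is.null(mk[[ev_id]])) mk[[ev_id]] <- mk_record()
      rec <- unclass(mk[[ev_id]]); rec[[dim]] <- value
      mk[[ev_id]] <- do.call(mk_record, as.list(rec))
    } else if (tag == "#") {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
      fields <- strsplit(parts[2L], " ", fixed = TRUE)[[1L]]
      if (fields[1L] == "CueLink" && length(fields) == 4L) {
        cue_links <- rbind(cue_links, data.frame(
          event_id = fields[2L], dimension = fields[3L], tb_id = fields[4L],
          stringsAsFactors = FALSE))
      }
    } else {
      stop(sprintf("unrecognised line in %s: %s", a2_file, line))
    }
  }
  .check_event_refs(events, textbounds, a2_file)
  for (ev_id in names(mk)) {
    if (!ev_id %in% names(events)) {
      stop(sprintf("attribute for unknown event %s in %s", ev_id, a2_file))
    }
  }
  if (nrow(cue_links)) {
    bad <- !(cue_links$tb_id %in% names(textbounds)) | !(cue_links$event_id %in% names(events))
    if (any(bad)) stop(sprintf("unresolved cue link in %s", a2_file))
  }
  if (length(textbounds)) {
    textbounds <- textbounds[order(as.integer(sub("^T", "", names(textbounds))))]
  }
  if (length(events)) {
    events <- events[order(as.integer(sub("^E", "", names(events))))]
  }
  rownames(cue_links) <- NULL
  structure(list(doc_id = doc_id, text = text, textbounds = textbounds,
                 events = events, mk = mk, cue_links = cue_links,
                 sentences = list()),
            class = "mk_document")
}

#' @exportS3Method base::print
print.mk_document <- function(x, ...) {
  cat(sprintf("<mk_document %s: %d chars, %d text-bounds, %d events, %d sentences>\n",
              x$doc_id, nchar(x$text), length(x$textbounds), length(x$events),
              length(x$sentences)))
  invisible(x)
}

.natural_order <- function(ids) order(as.integer(sub("^[TEA#]", "", ids)))

.format_tb_line <- function(tb) {
  offs <- paste(vapply(tb$fragments, function(f) paste(f, collapse = " "), character(1)),
                collapse = ";")
  sprintf("%s\t%s %s\t%s", tb$id, tb$kind, offs, tb$surface)
}

.format_event_line <- function(ev) {
  trig <- if (is.na(ev$trigger)) ev$type else paste0(ev$type, ":", ev$trigger)
  args <- vapply(ev$args, function(a) paste0(a$role, ":", a$ref), character(1))
  sprintf("%s\t%s", ev$id, paste(c(trig, args), collapse = " "))
}

#' Write a document back to standoff files
#'
#' Serialises an `mk_document` to `<dir>/<doc_id>.txt`, `.a1` and `.a2` (and
#' `.conll` when sentences are attached).  Output ordering is deterministic,
#' so `write -> read -> write` is byte-identical.
#'
#' @param doc an `mk_document`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_standoff <- function(doc, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, doc$doc_id)
  writeChar(doc$text, paste0(base, ".txt"), eos = NULL, useBytes = TRUE)

  tbs <- doc$textbounds[order(as.integer(sub("^T", "", names(doc$textbounds))))]
  a1 <- vapply(Filter(function(tb) tb$layer == "a1", tbs), .format_tb_line, character(1))
  writeLines(a1, paste0(base, ".a1"), useBytes = TRUE)

  a2 <- vapply(Filter(function(tb) tb$layer == "a2", tbs), .format_tb_line, character(1))
  evs <- doc$events[order(as.integer(sub("^E", "", names(doc$events))))]
  a2 <- c(a2, vapply(evs, .format_event_line, character(1)))
  k <- 0L
  for (ev in evs) {
    rec <- doc$mk[[ev$id]]
    if (is.null(rec)) next
    for (d in mk_dimensions()) {
      k <- k + 1L
      a2 <- c(a2, sprintf("A%d\t%s %s %s", k, d, ev$id, rec[[d]]))
    }
  }
  if (nrow(doc$cue_links)) {
    cl <- doc$cue_links[order(as.integer(sub("^E", "", doc$cue_links$event_id)),
                              match(doc$cue_links$dimension, mk_dimensions()),
                              as.integer(sub("^T", "", doc$cue_links$tb_id))), ]
    a2 <- c(a2, sprintf("#%d\tCueLink %s %s %s", seq_len(nrow(cl)),
                        cl$event_id, cl$dimension, cl$tb_id))
  }
  writeLines(a2, paste0(base, ".a2"), useBytes = TRUE)
  paths <- paste0(base, c(".txt", ".a1", ".a2"))
  if (length(doc$sentences)) {
    write_parse(doc, paste0(base, ".conll"))
    paths <- c(paths, paste0(base, ".conll"))
  }
  invisible(paths)
}

.align_tokens <- function(text, span, forms, file = "<parse>") {
  pos <- span[1L]
  n <- length(forms)
  starts <- integer(n); ends <- integer(n)
  for (i in seq_len(n)) {
    while (pos < span[2L] && grepl("^\\s$", .slice(text, pos, pos + 1L))) pos <- pos + 1L
    w <- nchar(forms[i])
    got <- .slice(text, pos, pos + w)
    if (!identical(got, forms[i])) {
      stop(sprintf("parse/text alignment error in %s at offset %d: expected '%s', found '%s'",
                   file, pos, forms[i], got))
    }
    starts[i] <- pos; ends[i] <- pos + w
    pos <- pos + w
  }
  list(start = starts, end = ends)
}

#' Attach token-aligned dependency parses to a document
#'
#' Reads a CoNLL-style parse file (columns INDEX, FORM, LEMMA, POS, HEAD,
#' DEPREL; one block per sentence per parser, each introduced by a comment
#' `# sent <index> <start> <end> <parser>`) and attaches sentences with
#' tokens and labelled dependency graphs to the document.  Token character
#' offsets are recovered by exact alignment of the FORM sequence against the
#' sentence text (whitespace between tokens is skipped); any mismatch is an
#' error naming the first offending offset.  Multiple parsers per sentence
#' are supported; their token FORM sequences must agree.
#'
#' @param parse_file path to the `.conll` file.
#' @param doc an `mk_document`.
#' @return The document with `sentences` populated.  Each sentence holds
#'   `index`, `span`, a `tokens` data frame (`index`, `surface`, `lemma`,
#'   `pos`, `start`, `end`) and `graphs`, a named list (one per parser) of
#'   edge data frames (`head`, `dep`, `rel`; `head == 0` marks the root).
#' @export
read_parse <- function(parse_file, doc) {
  lines <- readLines(parse_file, encoding = "UTF-8")
  sentences <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    if (!startsWith(lines[i], "# sent ")) {
      stop(sprintf("expected '# sent' comment in %s at line %d", parse_file, i))
    }
    hdr <- strsplit(sub("^# sent ", "", lines[i]), " ", fixed = TRUE)[[1L]]
    s_idx <- as.integer(hdr[1L]); span <- as.integer(hdr[2:3]); parser <- hdr[4L]
    i <- i + 1L
    rows <- character()
    while (i <= length(lines) && nzchar(lines[i])) { rows <- c(rows, lines[i]); i <- i + 1L }
    mat <- do.call(rbind, strsplit(rows, "\t", fixed = TRUE))
    if (ncol(mat) != 6L) stop(sprintf("expected 6 columns in %s near sentence %d", parse_file, s_idx))
    forms <- mat[, 2L]
    edges <- data.frame(head = as.integer(mat[, 5L]), dep = as.integer(mat[, 1L]),
                        rel = mat[, 6L], stringsAsFactors = FALSE)
    nt <- nrow(mat)
    if (any(edges$head < 0L | edges$head > nt)) {
      stop(sprintf("edge endpoint out of range in %s, sentence %d", parse_file, s_idx))
    }
    key <- as.character(s_idx)
    if (is.null(sentences[[key]])) {
      al <- .align_tokens(doc$text, span, forms, parse_file)
      tokens <- data.frame(index = as.integer(mat[, 1L]), surface = forms,
                           lemma = mat[, 3L], pos = mat[, 4L],
                           start = al$start, end = al$end, stringsAsFactors = FALSE)
      sentences[[key]] <- list(index = s_idx, span = span, tokens = tokens,
                               graphs = setNames(list(edges), parser))
    } else {
      if (!identical(sentences[[key]]$tokens$surface, forms)) {
        stop(sprintf("parser token mismatch in %s, sentence %d", parse_file, s_idx))
      }
      sentences[[key]]$graphs[[parser]] <- edges
    }
  }
  sentences <- sentences[order(vapply(sentences, `[[`, integer(1), "index"))]
  doc$sentences <- unname(sentences)
  doc
}

#' Write attached parses to a CoNLL-style file
#' @param doc an `mk_document` with sentences attached.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_parse <- function(doc, file) {
  out <- character()
  for (s in doc$sentences) {
    for (parser in names(s$graphs)) {
      g <- s$graphs[[parser]]
      g <- g[order(g$dep), ]
      out <- c(out, sprintf("# sent %d %d %d %s", s$index, s$span[1L], s$span[2L], parser),
               sprintf("%d\t%s\t%s\t%s\t%d\t%s", s$tokens$index, s$tokens$surface,
                       s$tokens$lemma, s$tokens$pos, g$head, g$rel),
               "")
    }
  }
  writeLines(out, file, useBytes = TRUE)
  invisible(file)
}

#' Remove events without an explicit trigger
#'
#' Trigger-less events cannot support trigger-anchored feature extraction and
#' are dropped.  Any event whose argument event was removed is removed
#' transitively, so no dangling reference survives.
#'
#' @param doc an `mk_document`.
#' @return The filtered document; the number of removed events is stored in
#'   `attr(, "removed_events")` and reported via `message()`.
#' @export
filter_triggerless_events <- function(doc) {
  keep <- vapply(doc$events, function(ev) !is.na(ev$trigger), logical(1))
  repeat {
    kept_ids <- names(doc$events)[keep]
    drop_more <- vapply(doc$events, function(ev) {
      any(vapply(ev$args, function(a) startsWith(a$ref, "E") && !a$ref %in% kept_ids,
                 logical(1)))
    }, logical(1))
    new_keep <- keep & !drop_more
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  removed <- sum(!keep)
  removed_ids <- names(doc$events)[!keep]
  doc$events <- doc$events[keep]
  doc$mk <- doc$mk[names(doc$mk) %in% names(doc$events)]
  if (nrow(doc$cue_links)) {
    doc$cue_links <- doc$cue_links[doc$cue_links$event_id %in% names(doc$events), ,
                                   drop = FALSE]
    rownames(doc$cue_links) <- NULL
  }
  if (removed > 0L) {
    message(sprintf("%s: removed %d trigger-less (or dangling) event(s): %s",
                    doc$doc_id, removed, paste(removed_ids, collapse = ", ")))
  }
  attr(doc, "removed_events") <- removed
  doc
}

#' Re-validate an annotated document
#'
#' Checks surface/offset agreement of every text-bound, reference resolution
#' and acyclicity of events, and (when sentences are attached) that every
#' event trigger lies within some sentence span.
#'
#' @param doc an `mk_document`.
#' @return `TRUE` invisibly; stops with an informative error otherwise.
#' @export
validate_document <- function(doc) {
  for (tb in doc$textbounds) {
    if (tb$span[1L] < 0L || tb$span[2L] > nchar(doc$text)) {
      stop(sprintf("%s: span of %s out of range", doc$doc_id, tb$id))
    }
    if (!identical(.tb_surface(doc$text, tb$fragments), tb$surface)) {
      stop(sprintf("%s: surface mismatch for %s", doc$doc_id, tb$id))
    }
  }
  .check_event_refs(doc$events, doc$textbounds, doc$doc_id)
  if (length(doc$sentences)) {
    spans <- vapply(doc$sentences, `[[`, integer(2), "span")
    for (ev in doc$events) {
      if (is.na(ev$trigger)) next
      tsp <- doc$textbounds[[ev$trigger]]$span
      inside <- any(spans[1L, ] <= tsp[1L] & tsp[2L] <= spans[2L, ])
      if (!inside) stop(sprintf("%s: trigger %s of %s outside all sentence spans",
                                doc$doc_id, ev$trigger, ev$id))
    }
  }
  invisible(TRUE)
}

#' Read a whole corpus directory
#'
#' Reads every `<id>.txt` under `dir` together with its `.a1`, `.a2` and
#' (when present) `.conll` files.
#'
#' @param dir corpus directory.
#' @return Named list of `mk_document`s keyed by document id.
#' @export
read_corpus <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- list()
  for (txt in txts) {
    id <- sub("\\.txt$", "", basename(txt))
    doc <- read_standoff(txt, file.path(dir, paste0(id, ".a1")),
                         file.path(dir, paste0(id, ".a2")), doc_id = id)
    conll <- file.path(dir, paste0(id, ".conll"))
    if (file.exists(conll)) doc <- read_parse(conll, doc)
    docs[[id]] <- doc
  }
  docs
}

#' Write a whole corpus to a directory
#' @param docs named list of `mk_document`s.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_corpus <- function(docs, dir) {
  for (doc in docs) write_standoff(doc, dir)
  invisible(dir)
}

# --- internal lookups shared by downstream modules ---------------------------

# sentence index containing a character span, or NA
.sentence_of_span <- function(doc, span) {
  for (k in seq_along(doc$sentences)) {
    s <- doc$sentences[[k]]
    if (s$span[1L] <= span[1L] && span[2L] <= s$span[2L]) return(k)
  }
  NA_integer_
}

# head token (row index into sentence$tokens) of a mention span within a
# sentence: the covered token whose head lies outside the covered set, else
# the last covered token.
.head_token <- function(sentence, span, parser = names(sentence$graphs)[1L]) {
  tok <- sentence$tokens
  covered <- which(tok$start < span[2L] & tok$end > span[1L])
  if (length(covered) == 0L) {
    # fall back to the token containing the span start
    covered <- which(tok$start <= span[1L] & tok$end > span[1L])
    if (length(covered) == 0L) return(NA_integer_)
  }
  if (length(covered) == 1L) return(covered)
  g <- sentence$graphs[[parser]]
  heads <- g$head[match(tok$index[covered], g$dep)]
  outside <- covered[!(heads %in% tok$index[covered])]
  if (length(outside)) outside[1L] else covered[length(covered)]
}

# trigger span of an event, following event-valued arguments to their trigger
.event_anchor_span <- function(doc, ref) {
  if (startsWith(ref, "T")) return(doc$textbounds[[ref]]$span)
  ev <- doc$events[[ref]]
  if (is.null(ev) || is.na(ev$trigger)) return(NULL)
  doc$textbounds[[ev$trigger]]$span
}
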