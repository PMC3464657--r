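# Meta-knowledge assignment pipeline
# ----------------------------------
# Per event, the feature vector is the type-normalised hash of:
#   cue-path features        (shortest paths participants <-> cue mentions)
#   trigger features         (neighbouring word function on the trigger)
#   trigger-argument pairs   (pair n-gram function, trigger vs each argument)
#   sentence features        (absolute + relative sentence position)
#   citation feature         (bracketed-number / year-parenthesis regex)
#   stacked scores           (optional: decision scores of an auxiliary model)
# Feature groups from different parsers get parser-distinct tags.  Ablation
# disables whole groups by base tag; this reproduces the minus-one-feature
# experimental grid.

.base_tag <- function(tag) sub("@.*$", "", tag)

# participant head tokens of an event within its sentence; arguments are
# entity spans, or the argument event's trigger span for nested events
.participants <- function(event, doc, sentence, parser) {
  spans <- list(doc$textbounds[[event$trigger]]$span)
  for (a in event$args) {
    sp <- .event_anchor_span(doc, a$ref)
    if (is.null(sp)) next
    spans[[length(spans) + 1L]] <- sp
  }
  idx <- integer()
  for (sp in spans) {
    if (sp[1L] >= sentence$span[1L] && sp[2L] <= sentence$span[2L]) {
      h <- .head_token(sentence, sp, parser)
      if (!is.na(h)) idx <- c(idx, h)
    }
  }
  unique(idx)
}

# feature groups for one event; `mentions` are precomputed cue matches for
# the event's sentence
.event_groups <- function(event, doc, sent_idx, mentions, config,
                          disable = character()) {
  sentence <- doc$sentences[[sent_idx]]
  groups <- list()
  trig_span <- doc$textbounds[[event$trigger]]$span
  for (parser in names(sentence$graphs)) {
    g <- sentence$graphs[[parser]]
    trig_tok <- .head_token(sentence, trig_span, parser)
    if (is.na(trig_tok)) next
    adj <- .adjacency(g, nrow(sentence$tokens))
    if (!"cue-path" %in% disable) {
      parts <- .participants(event, doc, sentence, parser)
      groups[[length(groups) + 1L]] <-
        cue_path_features(parts, mentions, sentence, g, config,
                          tag = paste0("cue-path@", parser), adj = adj)
    }
    if (!"trigger" %in% disable) {
      groups[[length(groups) + 1L]] <-
        neighbouring_word_features(trig_tok, sentence, g, config,
                                   tag = paste0("trigger@", parser), adj = adj)
    }
  }
  if (!"pair" %in% disable) {
    parser1 <- names(sentence$graphs)[1L]
    trig_tok <- .head_token(sentence, trig_span, parser1)
    names_pair <- .fg(tag = "pair", character())
    for (a in event$args) {
      sp <- .event_anchor_span(doc, a$ref)
      if (is.null(sp) || sp[1L] < sentence$span[1L] || sp[2L] > sentence$span[2L]) next
      arg_tok <- .head_token(sentence, sp, parser1)
      if (is.na(arg_tok) || is.na(trig_tok)) next
      pg <- pair_ngram_features(trig_tok, arg_tok, sentence, config, tag = "pair")
      names_pair$names <- c(names_pair$names, paste0(a$role, "|", pg$names))
      names_pair$values <- c(names_pair$values, pg$values)
    }
    groups[[length(groups) + 1L]] <- names_pair
  }
  if (!"sentence" %in% disable) {
    groups[[length(groups) + 1L]] <-
      sentence_position_features(sentence$index, length(doc$sentences))
  }
  if (!"citation" %in% disable) {
    stext <- .slice(doc$text, sentence$span[1L], sentence$span[2L])
    cit <- detect_citations(stext)
    groups[[length(groups) + 1L]] <-
      .fg("citation", if (cit$flag) "has_citation" else character())
  }
  groups
}

#' Decision-score stacking features from an auxiliary model
#'
#' Emits one real-valued feature per (dimension, value) of the scheme — 16
#' for the full scheme — holding the auxiliary model's decision score for
#' this instance, as a distinct feature group so that type-based
#' normalisation applies to it.
#'
#' @param vec a `hashed_vector` built with the auxiliary model's own lexicon
#'   and feature configuration.
#' @param aux an `mk_models` bundle, or `NULL` (returns an empty group, and
#'   the pipeline proceeds identically to the non-stacked one).
#' @return A feature group tagged `"stacked-score"`.
#' @export
stack_scores <- function(vec, aux) {
  if (is.null(aux)) return(.fg("stacked-score", character()))
  X <- .stack_hashed(list(vec))
  nm <- character(); val <- numeric()
  for (d in mk_dimensions()) {
    S <- predict_scores(aux$models[[d]], X)
    keep <- is.finite(S[1L, ])
    nm <- c(nm, paste0(d, ":", colnames(S)[keep]))
    val <- c(val, S[1L, keep])
  }
  .fg("stacked-score", nm, val)
}

# cue matches for every sentence of a document, cached
.doc_mentions <- function(doc, lexicon) {
  lapply(doc$sentences, function(s) {
    if (is.null(lexicon) || !nrow(lexicon)) list() else match_cues(s, lexicon)
  })
}

# build feature groups (and optionally the auxiliary stacked group) for the
# given events; returns a list parallel to `events`
.build_groups <- function(events, doc_index, lexicon, config,
                          disable = character(), aux = NULL) {
  mention_cache <- list()
  aux_mention_cache <- list()
  out <- vector("list", length(events))
  for (n in seq_along(events)) {
    e <- events[[n]]
    doc <- doc_index[[e$doc]]
    if (is.null(mention_cache[[e$doc]])) {
      mention_cache[[e$doc]] <- .doc_mentions(doc, lexicon)
    }
    ev <- doc$events[[e$event]]
    groups <- .event_groups(ev, doc, e$sentence,
                            mention_cache[[e$doc]][[e$sentence]], config, disable)
    if (!is.null(aux) && !"stacked" %in% disable) {
      if (is.null(aux_mention_cache[[e$doc]])) {
        aux_mention_cache[[e$doc]] <- .doc_mentions(doc, aux$lexicon)
      }
      aux_groups <- .event_groups(ev, doc, e$sentence,
                                  aux_mention_cache[[e$doc]][[e$sentence]],
                                  aux$feature_config, aux$disable)
      aux_vec <- normalise_typewise(aux_groups, aux$feature_config)
      groups[[length(groups) + 1L]] <- stack_scores(aux_vec, aux)
    }
    out[[n]] <- groups
  }
  out
}

#' Extract the classification instance of one event
#'
#' Builds all feature groups of the event from its own sentence and document
#' context, applies type-based normalisation and hashing, and returns the
#' instance.
#'
#' @param event_id event identifier within `doc`.
#' @param doc a parsed `mk_document`.
#' @param lexicon a `cue_lexicon` (or `NULL` for no cue features).
#' @param config a [feature_config()].
#' @param disable base tags of feature groups to drop (`"cue-path"`,
#'   `"trigger"`, `"pair"`, `"sentence"`, `"citation"`, `"stacked"`).
#' @param aux optional auxiliary `mk_models` bundle for score stacking.
#' @return List with `vector` (a `hashed_vector`), `groups` (the named
#'   feature groups) and `event` (the id).
#' @export
extract_mk_instance <- function(event_id, doc, lexicon, config = feature_config(),
                                disable = character(), aux = NULL) {
  ev <- doc$events[[event_id]]
  if (is.null(ev)) stop(sprintf("no event %s in %s", event_id, doc$doc_id))
  if (is.na(ev$trigger)) stop(sprintf("event %s has no trigger", event_id))
  k <- .sentence_of_span(doc, doc$textbounds[[ev$trigger]]$span)
  if (is.na(k)) stop(sprintf("trigger of %s lies outside all sentence spans", event_id))
  doc_index <- setNames(list(doc), doc$doc_id)
  groups <- .build_groups(list(list(doc = doc$doc_id, event = event_id, sentence = k)),
                          doc_index, lexicon, config, disable, aux)[[1L]]
  list(vector = normalise_typewise(groups, config), groups = groups,
       event = event_id)
}

#' Train the five per-dimension classifier sets
#'
#' Extracts one instance per gold-annotated event and trains an independent
#' one-vs-rest model set per dimension, with class-biased regularisation
#' factors and type-based feature normalisation (both disconnectable).
#'
#' @param docs named list of parsed `mk_document`s with gold meta-knowledge.
#' @param lexicon a `cue_lexicon`.
#' @param config a [feature_config()].
#' @param train_config a [training_config()].
#' @param disable feature groups to ablate (see [extract_mk_instance()]).
#' @param type_norm apply type-based normalisation (default `TRUE`; when
#'   `FALSE`, groups are hashed without any scaling).
#' @param aux optional auxiliary `mk_models` bundle whose decision scores are
#'   stacked as additional features.
#' @return An `mk_models` bundle: per-dimension `mk_model_set`s plus the
#'   configuration and lexicon checksum needed to reproduce the features at
#'   prediction time.
#' @export
train_mk <- function(docs, lexicon, config = feature_config(),
                     train_config = training_config(), disable = character(),
                     type_norm = TRUE, aux = NULL) {
  evs <- .corpus_events(docs, require_mk = TRUE)
  if (!length(evs)) stop("no trainable events (gold meta-knowledge + parses required)")
  doc_index <- setNames(docs, vapply(docs, `[[`, character(1), "doc_id"))
  groups_list <- .build_groups(evs, doc_index, lexicon, config, disable, aux)
  vecs <- lapply(groups_list, function(g) {
    if (type_norm) normalise_typewise(g, config) else hash_features(g, config)
  })
  X <- .stack_hashed(vecs)
  checksum <- .lexicon_checksum(lexicon)
  models <- list()
  for (d in mk_dimensions()) {
    labels <- vapply(evs, function(e) doc_index[[e$doc]]$mk[[e$event]][[d]], character(1))
    present <- mk_scheme()[[d]] %in% labels
    if (!all(present)) {
      warning(sprintf("dimension %s: value(s) %s absent from training data",
                      d, paste(mk_scheme()[[d]][!present], collapse = ", ")))
    }
    models[[d]] <- train_ovr(X, labels, values = mk_scheme()[[d]],
                             config = train_config, dimension = d,
                             lexicon_checksum = checksum)
  }
  structure(list(models = models, feature_config = config,
                 training_config = train_config, disable = disable,
                 type_norm = type_norm, lexicon = lexicon,
                 lexicon_checksum = checksum, stacked = !is.null(aux)),
            class = "mk_models")
}

#' @exportS3Method base::print
print.mk_models <- function(x, ...) {
  cat(sprintf("<mk_models: %s; hash bits %d; disabled [%s]%s>\n",
              paste(names(x$models), collapse = ", "),
              x$feature_config$hash_bits, paste(x$disable, collapse = ", "),
              if (x$stacked) "; stacked" else ""))
  invisible(x)
}

#' Assign meta-knowledge to every event of a corpus
#'
#' Every event with a trigger in a parsed sentence receives exactly one value
#' per dimension via highest-score one-vs-rest prediction; events whose
#' features cannot be extracted receive the scheme defaults.  Matched cue
#' mentions are recorded in the returned report.
#'
#' @param docs named list of parsed `mk_document`s.
#' @param bundle an `mk_models` bundle from [train_mk()].
#' @param lexicon the `cue_lexicon` to match cues with; must be the lexicon
#'   the bundle was trained with (checksum-guarded hard error otherwise).
#' @param aux optional auxiliary bundle (must match the training setup).
#' @return List with `docs` (documents with `mk` filled in, hyper-dimensions
#'   included as attributes of each record) and `cues`, a data frame of
#'   matched cue mentions (`doc_id`, `event_id`, `dimension`, `value`,
#'   `word`, `start`, `end`).
#' @export
assign_metaknowledge <- function(docs, bundle, lexicon = bundle$lexicon,
                                 aux = NULL) {
  if (!identical(.lexicon_checksum(lexicon), bundle$lexicon_checksum)) {
    stop("lexicon checksum mismatch: models were trained with a different lexicon")
  }
  if (bundle$stacked && is.null(aux)) {
    stop("models were trained with stacked auxiliary scores; supply `aux`")
  }
  doc_index <- setNames(docs, vapply(docs, `[[`, character(1), "doc_id"))
  evs <- .corpus_events(docs, require_mk = FALSE)
  cues <- list()
  if (length(evs)) {
    groups_list <- .build_groups(evs, doc_index, bundle$lexicon,
                                 bundle$feature_config, bundle$disable, aux)
    vecs <- lapply(groups_list, function(g) {
      if (bundle$type_norm) normalise_typewise(g, bundle$feature_config)
      else hash_features(g, bundle$feature_config)
    })
    X <- .stack_hashed(vecs)
    preds <- lapply(mk_dimensions(), function(d)
      predict_single_label(bundle$models[[d]], X))
    names(preds) <- mk_dimensions()
    mention_cache <- list()
    for (n in seq_along(evs)) {
      e <- evs[[n]]
      rec <- mk_record(KT = preds$KT[n], CL = preds$CL[n],
                       Polarity = preds$Polarity[n], Manner = preds$Manner[n],
                       Source = preds$Source[n])
      attr(rec, "hyper") <- derive_hyperdimensions(rec)
      doc_index[[e$doc]]$mk[[e$event]] <- rec
      if (is.null(mention_cache[[e$doc]])) {
        mention_cache[[e$doc]] <- .doc_mentions(doc_index[[e$doc]], bundle$lexicon)
      }
      for (m in mention_cache[[e$doc]][[e$sentence]]) {
        cues[[length(cues) + 1L]] <- data.frame(
          doc_id = e$doc, event_id = e$event,
          dimension = m$entries$dimension, value = m$entries$value,
          word = m$word, start = m$span[1L], end = m$span[2L],
          stringsAsFactors = FALSE)
      }
    }
  }
  # events without extractable features (no parse coverage) get the defaults
  for (id in names(doc_index)) {
    covered <- vapply(evs[vapply(evs, function(e) e$doc == id, logical(1))],
                      `[[`, character(1), "event")
    for (ev in doc_index[[id]]$events) {
      if (!ev$id %in% covered && is.null(doc_index[[id]]$mk[[ev$id]])) {
        rec <- mk_record()
        attr(rec, "hyper") <- derive_hyperdimensions(rec)
        doc_index[[id]]$mk[[ev$id]] <- rec
      }
    }
  }
  cues_df <- if (length(cues)) do.call(rbind, cues) else
    data.frame(doc_id = character(), event_id = character(), dimension = character(),
               value = character(), word = character(), start = integer(),
               end = integer(), stringsAsFactors = FALSE)
  list(docs = doc_index, cues = cues_df)
}

# --- learned cue detection ---------------------------------------------------

# token-level training instances for the cue detector
.cue_token_instances <- function(docs, lexicon, config, dictionary_filter = TRUE) {
  insts <- list()
  for (doc in docs) {
    for (k in seq_along(doc$sentences)) {
      s <- doc$sentences[[k]]
      lem <- tolower(s$tokens$lemma)
      # gold cue labels per token from annotated cue text-bounds + event mk
      gold <- vector("list", nrow(s$tokens))
      for (tb in doc$textbounds) {
        if (!grepl("-cue$", tb$kind)) next
        if (tb$span[1L] < s$span[1L] || tb$span[2L] > s$span[2L]) next
        dim <- sub("-cue$", "", tb$kind)
        links <- doc$cue_links[doc$cue_links$tb_id == tb$id &
                                 doc$cue_links$dimension == dim, , drop = FALSE]
        vals <- unique(vapply(links$event_id, function(eid) {
          rec <- doc$mk[[eid]]
          if (is.null(rec)) NA_character_ else rec[[dim]]
        }, character(1)))
        vals <- vals[!is.na(vals)]
        covered <- which(s$tokens$start < tb$span[2L] & s$tokens$end > tb$span[1L])
        for (tk in covered) gold[[tk]] <- unique(c(gold[[tk]], paste0(dim, ":", vals)))
      }
      dict_words <- unique(unlist(strsplit(unique(lexicon$word), " ", fixed = TRUE)))
      for (tk in seq_len(nrow(s$tokens))) {
        is_dict <- lem[tk] %in% dict_words
        if (dictionary_filter && !is_dict && !length(gold[[tk]])) next
        insts[[length(insts) + 1L]] <- list(
          doc = doc$doc_id, sentence = k, token = tk,
          labels = if (length(gold[[tk]])) gold[[tk]] else "NONE")
      }
    }
  }
  insts
}

.cue_token_vector <- function(doc, k, tk, config) {
  s <- doc$sentences[[k]]
  groups <- list(token_features(s$tokens$surface[tk], tolower(s$tokens$lemma[tk]),
                                s$tokens$pos[tk], config))
  for (parser in names(s$graphs)) {
    groups[[length(groups) + 1L]] <-
      neighbouring_word_features(tk, s, s$graphs[[parser]], config,
                                 tag = paste0("neighbour@", parser))
  }
  normalise_typewise(groups, config)
}

#' Train a learned (token-level) cue detector
#'
#' Treats cue words as new classes of tokens: each candidate token is
#' classified into `<Dimension>:<Value>` cue classes (multi-label, since one
#' word can cue several dimensions) plus an explicit `NONE` class.  Training
#' candidates are dictionary-matching tokens plus all annotated cue tokens.
#'
#' @param docs parsed, cue-annotated training documents.
#' @param lexicon the cue dictionary used as candidate filter.
#' @param config a [feature_config()].
#' @param train_config a [training_config()].
#' @return An `mk_cue_detector`.
#' @export
train_cue_detector <- function(docs, lexicon, config = feature_config(),
                               train_config = training_config()) {
  doc_index <- setNames(docs, vapply(docs, `[[`, character(1), "doc_id"))
  insts <- .cue_token_instances(docs, lexicon, config)
  if (!length(insts)) stop("no cue-detector training instances")
  vecs <- lapply(insts, function(e)
    .cue_token_vector(doc_index[[e$doc]], e$sentence, e$token, config))
  X <- .stack_hashed(vecs)
  label_sets <- lapply(insts, `[[`, "labels")
  classes <- sort(unique(unlist(label_sets)))
  classes <- c(setdiff(classes, "NONE"), "NONE")
  # one-vs-rest over possibly multi-label gold: positive iff class in set
  active <- which(Matrix::colSums(X != 0) > 0)
  Xa <- X[, active, drop = FALSE]
  if (train_config$bias) Xa <- cbind(Xa, 1)
  W <- matrix(NA_real_, nrow = ncol(Xa), ncol = length(classes),
              dimnames = list(NULL, classes))
  for (cl in classes) {
    y <- ifelse(vapply(label_sets, function(ls) cl %in% ls, logical(1)), 1, -1)
    npos <- sum(y > 0)
    if (npos == 0L) next
    fac <- if (train_config$use_bias_factors) (length(y) - npos) / npos else 1
    cost <- ifelse(y > 0, train_config$C * fac, train_config$C)
    W[, cl] <- .fit_l2svm(Xa, y, cost, tol = train_config$tol,
                          maxit = train_config$maxit)
  }
  models <- structure(list(dimension = "cue", values = classes, active = active,
                           W = W, config = train_config, dim = ncol(X),
                           lexicon_checksum = .lexicon_checksum(lexicon)),
                      class = "mk_model_set")
  structure(list(models = models, feature_config = config,
                 lexicon_checksum = .lexicon_checksum(lexicon)),
            class = "mk_cue_detector")
}

#' Detect cues in a sentence with the learned detector
#'
#' @param doc a parsed `mk_document`.
#' @param sentence_index which sentence to scan.
#' @param detector an `mk_cue_detector`.
#' @param lexicon the cue dictionary (checksum-guarded).
#' @param dictionary_filter when `TRUE` (default) only tokens whose lemma
#'   matches a dictionary word are candidates; when `FALSE`, every token is.
#' @return List of cue mentions in the [match_cues()] format (entries carry
#'   `pmi = NA`).
#' @export
detect_cues_learned <- function(doc, sentence_index, detector, lexicon,
                                dictionary_filter = TRUE) {
  if (!identical(detector$lexicon_checksum, .lexicon_checksum(lexicon))) {
    stop("lexicon checksum mismatch for cue detector")
  }
  s <- doc$sentences[[sentence_index]]
  lem <- tolower(s$tokens$lemma)
  dict_words <- unique(unlist(strsplit(unique(lexicon$word), " ", fixed = TRUE)))
  cand <- if (dictionary_filter) which(lem %in% dict_words) else seq_along(lem)
  if (!length(cand)) return(list())
  vecs <- lapply(cand, function(tk)
    .cue_token_vector(doc, sentence_index, tk, detector$feature_config))
  X <- .stack_hashed(vecs)
  labs <- predict_multi_label(detector$models, X, none_class = "NONE")
  mentions <- list()
  for (n in seq_along(cand)) {
    if (!length(labs[[n]])) next
    tk <- cand[n]
    parts <- do.call(rbind, strsplit(labs[[n]], ":", fixed = TRUE))
    mentions[[length(mentions) + 1L]] <- list(
      span = c(s$tokens$start[tk], s$tokens$end[tk]),
      first_token = tk, last_token = tk, word = lem[tk],
      entries = data.frame(word = lem[tk], dimension = parts[, 1L],
                           value = parts[, 2L], pmi = NA_real_,
                           stringsAsFactors = FALSE))
  }
  mentions
}

# --- annotation transfer -----------------------------------------------------

# role + covering span signature of an event's core arguments
.arg_signature <- function(event, doc) {
  sig <- vapply(event$args, function(a) {
    sp <- .event_anchor_span(doc, a$ref)
    if (is.null(sp)) return(NA_character_)
    sprintf("%s:%d-%d", a$role, sp[1L], sp[2L])
  }, character(1))
  paste(sort(sig), collapse = ";")
}

#' Transfer meta-knowledge annotation between corpora
#'
#' Copies meta-knowledge from source events onto target events.  A transfer
#' happens only when the mapped source event matches the target event on
#' event type and on the role-labelled core-argument spans (exact offsets;
#' event-valued arguments are compared via their trigger span).  Ambiguous
#' multi-matches are skipped with a warning — the procedure is deliberately
#' conservative.
#'
#' @param source_docs named list of documents carrying meta-knowledge.
#' @param target_docs named list of documents to annotate (same underlying
#'   texts).
#' @param id_map data frame (`doc_id`, `source_id`, `target_id`) mapping
#'   event ids between the corpora.
#' @return List with `docs` (annotated targets) and `report`: `total`
#'   target events, `transferred`, `skipped`, and a per-event outcome data
#'   frame.
#' @export
transfer_annotations <- function(source_docs, target_docs, id_map) {
  stopifnot(all(c("doc_id", "source_id", "target_id") %in% names(id_map)))
  src_index <- setNames(source_docs, vapply(source_docs, `[[`, character(1), "doc_id"))
  out_docs <- setNames(target_docs, vapply(target_docs, `[[`, character(1), "doc_id"))
  rows <- list()
  transferred <- 0L; total <- 0L
  for (id in names(out_docs)) {
    tdoc <- out_docs[[id]]
    sdoc <- src_index[[id]]
    for (tev in tdoc$events) {
      total <- total + 1L
      outcome <- "no-map"
      hit <- id_map[id_map$doc_id == id & id_map$target_id == tev$id, , drop = FALSE]
      if (nrow(hit) > 1L) {
        warning(sprintf("ambiguous id map for %s/%s; skipped", id, tev$id))
        outcome <- "ambiguous"
      } else if (nrow(hit) == 1L && !is.null(sdoc)) {
        sev <- sdoc$events[[hit$source_id]]
        if (!is.null(sev) && identical(sev$type, tev$type) &&
            identical(.arg_signature(sev, sdoc), .arg_signature(tev, tdoc)) &&
            !is.null(sdoc$mk[[sev$id]])) {
          out_docs[[id]]$mk[[tev$id]] <- sdoc$mk[[sev$id]]
          transferred <- transferred + 1L
          outcome <- "transferred"
        } else {
          outcome <- "mismatch"
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(doc_id = id, target_id = tev$id,
                                              outcome = outcome,
                                              stringsAsFactors = FALSE)
    }
  }
  list(docs = out_docs,
       report = list(total = total, transferred = transferred,
                     skipped = total - transferred,
                     detail = do.call(rbind, rows)))
}
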