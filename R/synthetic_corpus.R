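# Synthetic corpus generator
# --------------------------
# Emits standoff corpora (text, entities, triggers, events, meta-knowledge,
# cue mentions) with parses known by construction, so the whole pipeline can
# be exercised without any corpus download.  Sentences follow two templates
# whose dependency trees place cue words in a preamble noun phrase, three
# dependency steps and more than three tokens away from the event trigger:
# cue evidence is then reachable by the shortest-path (cue-path) features but
# not by the 2-step neighbourhood or the +/-3-word windows, which is what the
# feature-ablation experiments exploit.  Default value distributions follow
# the per-dimension relative frequencies observed in the corpus the scheme
# was annotated on (about 5.3/17.8/34.7/8.1/2.7/31.4% for the KT values,
# 6.1% Negative polarity, 1.5% non-Current source, etc.).

.SYN_PROTEINS <- c("p53", "NF-kappaB", "TNF-alpha", "STAT3", "IL-2", "BCL-2",
                   "MYC", "EGFR", "AKT1", "FOXP3", "GATA3", "RELA", "JUN",
                   "FOS", "SMAD4", "NOTCH1", "CDK2", "TP73", "MDM2", "VEGF")

.SYN_FILLERS <- c("recent", "detailed", "careful", "broad", "joint", "large",
                  "early", "parallel")

.SYN_VERBS <- data.frame(
  surface = c("activates", "inhibits", "binds", "phosphorylates"),
  lemma = c("activate", "inhibit", "bind", "phosphorylate"),
  type = c("Positive_regulation", "Negative_regulation", "Binding",
           "Phosphorylation"),
  stringsAsFactors = FALSE)

.default_cue_inventory <- function() {
  rows <- rbind(
    c("investigative", "KT", "Investigation"),
    c("observed",      "KT", "Observation"),
    c("speculative",   "KT", "Analysis"),
    c("established",   "KT", "Fact"),
    c("methodological","KT", "Method"),
    c("probable",      "CL", "L2"),
    c("possible",      "CL", "L1"),
    c("contradictory", "Polarity", "Negative"),
    c("strong",        "Manner", "High"),
    c("weak",          "Manner", "Low"),
    c("previous",      "Source", "Other"))
  inv <- data.frame(word = rows[, 1L], dimension = rows[, 2L], value = rows[, 3L],
                    emission = 1, stringsAsFactors = FALSE)
  # shared ambiguous cue, used when cue_ambiguity > 0
  amb <- data.frame(word = "apparent",
                    dimension = inv$dimension, value = inv$value,
                    emission = 0, stringsAsFactors = FALSE)
  rbind(inv, amb)
}

#' Configuration of the synthetic corpus generator
#'
#' @param n_docs number of documents.
#' @param sentences_per_doc integer range `c(min, max)` of sentences per
#'   document.
#' @param value_dist named list (one element per dimension) of named
#'   probability vectors over that dimension's values; defaults follow the
#'   per-dimension value frequencies of the reference annotated corpus.
#' @param cue_inventory data frame (`word`, `dimension`, `value`,
#'   `emission`): the cue emitted when a sentence carries the value, with its
#'   emission probability.
#' @param cue_ambiguity probability that an emitted cue is replaced by the
#'   shared ambiguous cue word (default 0: cue-separable).
#' @param label_noise probability that a gold dimension value is resampled
#'   uniformly from the other values, without changing cues (default 0).
#' @param citation_prob probability of appending a citation string to a
#'   sentence (injected independently of the sampled meta-knowledge values).
#' @param kt_position_bias strength in `[0, 1]` of the document-position
#'   skew: Fact/Observation early, Analysis/Investigation late.
#' @param nested_rate probability that a sentence uses the nested-regulation
#'   template (two events, one the other's Theme).
#' @param seed random seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_docs = 50L,
                         sentences_per_doc = c(4L, 10L),
                         value_dist = NULL,
                         cue_inventory = .default_cue_inventory(),
                         cue_ambiguity = 0,
                         label_noise = 0,
                         citation_prob = 0.1,
                         kt_position_bias = 0.5,
                         nested_rate = 0.2,
                         seed = 1L) {
  if (is.null(value_dist)) {
    value_dist <- list(
      KT = c(Other = 0.314, Investigation = 0.053, Observation = 0.347,
             Analysis = 0.178, Fact = 0.081, Method = 0.027),
      CL = c(L3 = 0.919, L2 = 0.060, L1 = 0.021),
      Polarity = c(Positive = 0.939, Negative = 0.061),
      Manner = c(Neutral = 0.953, High = 0.038, Low = 0.009),
      Source = c(Current = 0.985, Other = 0.015))
  }
  for (d in mk_dimensions()) {
    p <- value_dist[[d]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-6 || any(p < 0) ||
        !all(names(p) %in% mk_scheme()[[d]])) {
      stop(sprintf("invalid value distribution for dimension %s", d))
    }
  }
  stopifnot(cue_ambiguity >= 0, cue_ambiguity <= 1,
            label_noise >= 0, label_noise <= 1,
            citation_prob >= 0, citation_prob <= 1,
            kt_position_bias >= 0, kt_position_bias <= 1,
            nested_rate >= 0, nested_rate <= 1,
            length(sentences_per_doc) == 2L,
            sentences_per_doc[1L] >= 1L,
            sentences_per_doc[2L] >= sentences_per_doc[1L])
  structure(list(n_docs = as.integer(n_docs),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 value_dist = value_dist, cue_inventory = cue_inventory,
                 cue_ambiguity = cue_ambiguity, label_noise = label_noise,
                 citation_prob = citation_prob,
                 kt_position_bias = kt_position_bias,
                 nested_rate = nested_rate, seed = as.integer(seed)),
            class = "synth_config")
}

# KT distribution reweighted by document position (relpos in (0, 1])
.kt_position_dist <- function(p, relpos, strength) {
  if (strength == 0) return(p)
  m <- setNames(rep(1, length(p)), names(p))
  early <- names(p) %in% c("Fact", "Observation")
  late <- names(p) %in% c("Analysis", "Investigation")
  m[early] <- pmax(0.1, 1 + strength * (1 - 2 * relpos))
  m[late] <- pmax(0.1, 1 + strength * (2 * relpos - 1))
  q <- p * m
  q / sum(q)
}

.sample_value <- function(p) sample(names(p), 1L, prob = p)

# one generated sentence: tokens (surface/lemma/pos), edges, event plan,
# cue slot bookkeeping
.gen_sentence <- function(cfg, relpos) {
  mk <- list()
  for (d in mk_dimensions()) {
    p <- cfg$value_dist[[d]]
    if (d == "KT") p <- .kt_position_dist(p, relpos, cfg$kt_position_bias)
    mk[[d]] <- .sample_value(p)
  }
  # cue slot words, one per dimension, in dimension order
  slot_word <- character(5L); slot_cue <- rep(NA_character_, 5L)
  defaults <- mk_defaults()
  for (si in seq_along(mk_dimensions())) {
    d <- mk_dimensions()[si]
    v <- mk[[d]]
    inv <- cfg$cue_inventory
    row <- inv[inv$dimension == d & inv$value == v & inv$emission > 0, , drop = FALSE]
    emit <- v != defaults[[d]] && nrow(row) > 0L &&
      stats::runif(1) < row$emission[1L]
    if (emit) {
      w <- row$word[1L]
      if (cfg$cue_ambiguity > 0 && stats::runif(1) < cfg$cue_ambiguity) {
        w <- "apparent"
      }
      slot_word[si] <- w
      slot_cue[si] <- d
    } else {
      slot_word[si] <- sample(.SYN_FILLERS, 1L)
    }
  }
  # label noise: resample the gold value, cues unchanged.  The variates are
  # drawn unconditionally so that corpora generated from the same seed with
  # different noise rates share sentences and cues, differing only in labels.
  for (d in mk_dimensions()) {
    u <- stats::runif(1)
    alt <- sample(setdiff(mk_scheme()[[d]], mk[[d]]), 1L)
    if (u < cfg$label_noise) mk[[d]] <- alt
  }
  agent <- sample(.SYN_PROTEINS, 1L)
  target <- sample(setdiff(.SYN_PROTEINS, agent), 1L)
  nested <- stats::runif(1) < cfg$nested_rate
  cite <- stats::runif(1) < cfg$citation_prob

  if (!nested) {
    vb <- .SYN_VERBS[sample.int(nrow(.SYN_VERBS), 1L), ]
    surf <- c("In", "a", slot_word, "study", "of", "cells", ",",
              agent, "protein", vb$surface, "the", target, "gene")
    lem <- c("in", "a", slot_word, "study", "of", "cell", ",",
             tolower(agent), "protein", vb$lemma, "the", tolower(target), "gene")
    pos <- c("IN", "DT", rep("JJ", 5L), "NN", "IN", "NNS", ",",
             "NN", "NN", "VBZ", "DT", "NN", "NN")
    # head/rel per token (root = trigger at 14)
    head <- c(14L, 8L, rep(8L, 5L), 1L, 8L, 9L, 14L, 14L, 12L, 0L, 16L, 14L, 16L)
    rel <- c("VMOD", "NMOD", rep("NMOD", 5L), "PMOD", "NMOD", "PMOD", "P",
             "SUB", "NMOD", "ROOT", "NMOD", "OBJ", "NMOD")
    trig_tok <- 14L; agent_tok <- 12L; target_tok <- 16L
    plan <- list(list(type = vb$type, trigger_tok = trig_tok,
                      args = if (vb$type == "Binding") {
                        list(list(role = "Theme", tok = agent_tok),
                             list(role = "Theme", tok = target_tok))
                      } else if (vb$type == "Phosphorylation") {
                        list(list(role = "Theme", tok = target_tok))
                      } else {
                        list(list(role = "Theme", tok = target_tok),
                             list(role = "Cause", tok = agent_tok))
                      }))
  } else {
    surf <- c("In", "a", slot_word, "study", "of", "cells", ",",
              agent, "protein", "induced", "expression", "of", "the",
              target, "gene")
    lem <- c("in", "a", slot_word, "study", "of", "cell", ",",
             tolower(agent), "protein", "induce", "expression", "of", "the",
             tolower(target), "gene")
    pos <- c("IN", "DT", rep("JJ", 5L), "NN", "IN", "NNS", ",",
             "NN", "NN", "VBD", "NN", "IN", "DT", "NN", "NN")
    head <- c(14L, 8L, rep(8L, 5L), 1L, 8L, 9L, 14L, 14L, 12L, 0L, 14L, 15L,
              18L, 16L, 18L)
    rel <- c("VMOD", "NMOD", rep("NMOD", 5L), "PMOD", "NMOD", "PMOD", "P",
             "SUB", "NMOD", "ROOT", "OBJ", "NMOD", "NMOD", "PMOD", "NMOD")
    agent_tok <- 12L; target_tok <- 18L
    plan <- list(
      list(type = "Gene_expression", trigger_tok = 15L,
           args = list(list(role = "Theme", tok = target_tok))),
      list(type = "Positive_regulation", trigger_tok = 14L,
           args = list(list(role = "Cause", tok = agent_tok),
                       list(role = "Theme", event_arg = 1L))))
  }
  if (cite) {
    num <- as.character(sample.int(200L, 1L))
    n0 <- length(surf)
    surf <- c(surf, "[", num, "]")
    lem <- c(lem, "[", num, "]")
    pos <- c(pos, "(", "CD", ")")
    root <- which(head == 0L)
    head <- c(head, root, root, root)
    rel <- c(rel, "P", "P", "P")
  }
  cue_slots <- which(!is.na(slot_cue))
  list(surface = surf, lemma = lem, pos = pos, head = head, rel = rel,
       mk = mk, plan = plan,
       entity_toks = c(agent = agent_tok, target = target_tok),
       cue_toks = 2L + cue_slots, cue_dims = slot_cue[cue_slots])
}

#' Generate a synthetic standoff corpus
#'
#' Builds `n_docs` documents of template sentences with dependency parses
#' known by construction, one or two events per sentence (trigger plus
#' Theme/Cause arguments, optionally a nested regulation), gold
#' meta-knowledge sampled from the configured per-dimension distributions
#' (with document-position bias for KT), cue words inserted for non-default
#' values, and citation strings appended probabilistically.  Defaults are
#' emitted with no cue.  All randomness comes from `config$seed`; the same
#' configuration always produces byte-identical output.
#'
#' @param config a [synth_config()].
#' @return Named list of `mk_document`s with sentences and parses attached,
#'   passing [validate_document()].
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  docs <- list()
  for (dn in seq_len(config$n_docs)) {
    doc_id <- sprintf("SYN%04d", dn)
    n_sent <- sample(seq(config$sentences_per_doc[1L], config$sentences_per_doc[2L]), 1L)
    sents <- lapply(seq_len(n_sent), function(s) .gen_sentence(config, s / n_sent))
    # assemble text and offsets
    text <- ""
    pos0 <- 0L
    textbounds <- list(); events <- list(); mk <- list()
    cue_rows <- list()
    sentences <- list()
    t_id <- 0L; e_id <- 0L
    for (s_idx in seq_len(n_sent)) {
      sn <- sents[[s_idx]]
      n_tok <- length(sn$surface)
      starts <- integer(n_tok); ends <- integer(n_tok)
      p <- pos0
      for (tk in seq_len(n_tok)) {
        if (tk > 1L) p <- p + 1L  # single space between tokens
        starts[tk] <- p; ends[tk] <- p + nchar(sn$surface[tk])
        p <- ends[tk]
      }
      sent_text <- paste(sn$surface, collapse = " ")
      text <- if (nzchar(text)) paste0(text, " ", sent_text) else sent_text
      span <- c(starts[1L], ends[n_tok])
      pos0 <- ends[n_tok] + 1L
      tokens <- data.frame(index = seq_len(n_tok), surface = sn$surface,
                           lemma = sn$lemma, pos = sn$pos,
                           start = starts, end = ends, stringsAsFactors = FALSE)
      edges <- data.frame(head = sn$head, dep = seq_len(n_tok), rel = sn$rel,
                          stringsAsFactors = FALSE)
      sentences[[s_idx]] <- list(index = s_idx, span = as.integer(span),
                                 tokens = tokens,
                                 graphs = list(synth = edges))
      tb_of_tok <- function(tk, kind, layer) {
        t_id <<- t_id + 1L
        id <- paste0("T", t_id)
        textbounds[[id]] <<- new_textbound(id, kind,
                                           list(c(starts[tk], ends[tk])),
                                           sn$surface[tk], layer)
        id
      }
      ent_ids <- c(agent = tb_of_tok(sn$entity_toks[["agent"]], "Protein", "a1"),
                   target = tb_of_tok(sn$entity_toks[["target"]], "Protein", "a1"))
      sent_event_ids <- character(length(sn$plan))
      for (pi in seq_along(sn$plan)) {
        pl <- sn$plan[[pi]]
        trig_id <- tb_of_tok(pl$trigger_tok, pl$type, "a2")
        e_id <- e_id + 1L
        ev_id <- paste0("E", e_id)
        args <- lapply(pl$args, function(a) {
          if (!is.null(a$event_arg)) {
            list(role = a$role, ref = sent_event_ids[a$event_arg])
          } else {
            ref <- if (a$tok == sn$entity_toks[["agent"]]) ent_ids[["agent"]]
                   else ent_ids[["target"]]
            list(role = a$role, ref = ref)
          }
        })
        events[[ev_id]] <- new_event(ev_id, pl$type, trig_id, args)
        sent_event_ids[pi] <- ev_id
        mk[[ev_id]] <- do.call(mk_record, sn$mk)
      }
      # cue text-bounds + links to every event of the sentence
      for (ci in seq_along(sn$cue_toks)) {
        tk <- sn$cue_toks[ci]; d <- sn$cue_dims[ci]
        cue_id <- tb_of_tok(tk, paste0(d, "-cue"), "a2")
        for (ev_id in sent_event_ids) {
          cue_rows[[length(cue_rows) + 1L]] <- data.frame(
            event_id = ev_id, dimension = d, tb_id = cue_id,
            stringsAsFactors = FALSE)
        }
      }
    }
    cue_links <- if (length(cue_rows)) do.call(rbind, cue_rows) else
      data.frame(event_id = character(), dimension = character(),
                 tb_id = character(), stringsAsFactors = FALSE)
    if (nrow(cue_links)) {
      # canonical (writer) order, so write -> read round-trips field-for-field
      cue_links <- cue_links[order(as.integer(sub("^E", "", cue_links$event_id)),
                                   match(cue_links$dimension, mk_dimensions()),
                                   as.integer(sub("^T", "", cue_links$tb_id))), ,
                             drop = FALSE]
    }
    rownames(cue_links) <- NULL
    docs[[doc_id]] <- structure(
      list(doc_id = doc_id, text = text, textbounds = textbounds,
           events = events, mk = mk, cue_links = cue_links,
           sentences = sentences),
      class = "mk_document")
  }
  docs
}

#' Generate a source/target corpus pair with an event id map
#'
#' Produces a fixture for [transfer_annotations()]: the target corpus is a
#' copy of the source with event ids renumbered (reversed within each
#' document), gold meta-knowledge stripped, a configurable fraction of
#' events kept, and a configurable fraction perturbed (event type changed or
#' an argument retargeted) so that the conservative transfer rule must skip
#' them.
#'
#' @param config a [synth_config()].
#' @param keep_fraction fraction of source events present in the target
#'   (argument events of kept events are kept too).
#' @param perturb_fraction fraction of kept target events perturbed.
#' @return List with `source` (docs with meta-knowledge), `target` (docs
#'   without), and `id_map` (data frame `doc_id`, `source_id`, `target_id`).
#' @export
generate_idmapped_pair <- function(config = synth_config(),
                                   keep_fraction = 1, perturb_fraction = 0) {
  stopifnot(keep_fraction >= 0, keep_fraction <= 1,
            perturb_fraction >= 0, perturb_fraction <= 1)
  source <- generate_corpus(config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed + 77L)
  target <- list()
  maps <- list()
  for (id in names(source)) {
    doc <- source[[id]]
    ids <- names(doc$events)
    keep <- ids[sort(sample.int(length(ids), round(keep_fraction * length(ids))))]
    # close downwards over event-valued arguments
    repeat {
      need <- unlist(lapply(doc$events[keep], function(ev) {
        refs <- vapply(ev$args, `[[`, character(1), "ref")
        refs[startsWith(refs, "E")]
      }), use.names = FALSE)
      add <- setdiff(need, keep)
      if (!length(add)) break
      keep <- c(keep, add)
    }
    keep <- ids[ids %in% keep]
    # reversed renumbering
    new_ids <- setNames(paste0("E", rev(seq_along(keep))), keep)
    evs <- list()
    for (old in keep) {
      ev <- doc$events[[old]]
      ev$id <- new_ids[[old]]
      ev$args <- lapply(ev$args, function(a) {
        if (startsWith(a$ref, "E")) a$ref <- new_ids[[a$ref]]
        a
      })
      evs[[ev$id]] <- ev
    }
    evs <- evs[order(as.integer(sub("^E", "", names(evs))))]
    # perturb a fraction of the kept events
    n_pert <- round(perturb_fraction * length(evs))
    pert <- if (n_pert > 0) sort(sample.int(length(evs), n_pert)) else integer()
    for (kk in pert) {
      ev <- evs[[kk]]
      if (stats::runif(1) < 0.5 || length(ev$args) < 2L) {
        ev$type <- sample(setdiff(unique(c(.SYN_VERBS$type, "Gene_expression",
                                           "Positive_regulation")), ev$type), 1L)
      } else {
        # swap the referents of the first two arguments
        tmp <- ev$args[[1L]]$ref
        ev$args[[1L]]$ref <- ev$args[[2L]]$ref
        ev$args[[2L]]$ref <- tmp
      }
      evs[[kk]] <- ev
    }
    tdoc <- doc
    tdoc$events <- evs
    tdoc$mk <- list()
    tdoc$cue_links <- tdoc$cue_links[0L, , drop = FALSE]
    rownames(tdoc$cue_links) <- NULL
    target[[id]] <- tdoc
    if (length(keep)) {
      maps[[length(maps) + 1L]] <- data.frame(
        doc_id = id, source_id = keep, target_id = unname(new_ids[keep]),
        stringsAsFactors = FALSE)
    }
  }
  id_map <- if (length(maps)) do.call(rbind, maps) else
    data.frame(doc_id = character(), source_id = character(),
               target_id = character(), stringsAsFactors = FALSE)
  rownames(id_map) <- NULL
  list(source = source, target = target, id_map = id_map)
}
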