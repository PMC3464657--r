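# Feature extraction
# ------------------
# Five base feature functions (token, neighbouring word, word n-gram, pair
# n-gram, shortest dependency path) plus the meta-knowledge-specific features
# (cue paths, sentence position, citation), all emitting named feature
# groups.  Groups are hashed into a fixed 2^bits sparse space; type-based
# normalisation scales each group to unit L2 length before hashing and the
# concatenated hashed vector to unit L2 length afterwards.
#
# Feature-name grammar: every name is "<prefix>:<payload>".  Words in
# n-grams are lemmas; directed dependency edges between a left word L and a
# right word R are rendered "←REL–" when L is the head and
# "–REL→" when R is the head.  "Mixed" n-grams count alternating
# word/edge elements, so n = 3 spans e.g. word-edge-word.

.ARROW_L <- "←"  # <-
.ARROW_R <- "→"  # ->
.DASH <- "–"     # en dash

#' Feature extraction configuration
#'
#' @param char_ngrams character n-gram orders for token features.
#' @param window context window in words on each side for (pair) n-gram
#'   features.
#' @param neighbour_depth maximum dependency-path length for neighbouring
#'   word features.
#' @param hash_bits hashed space is `2^hash_bits` (default 20).
#' @return A `feature_config` list.
#' @export
feature_config <- function(char_ngrams = 1:4, window = 3L, neighbour_depth = 2L,
                           hash_bits = 20L) {
  stopifnot(all(char_ngrams >= 1L), window >= 1L, neighbour_depth >= 1L,
            hash_bits >= 1L, hash_bits <= 30L)
  structure(list(char_ngrams = as.integer(char_ngrams), window = as.integer(window),
                 neighbour_depth = as.integer(neighbour_depth),
                 hash_bits = as.integer(hash_bits)),
            class = "feature_config")
}

# A feature group is a tag plus parallel name/value vectors (names may
# repeat; duplicates sum on collapse).
.fg <- function(tag, names, values = rep(1, length(names))) {
  structure(list(tag = tag, names = as.character(names), values = as.numeric(values)),
            class = "feature_group")
}

.fg_collapse <- function(g) {
  if (!length(g$names)) return(g)
  v <- rowsum(g$values, g$names)
  .fg(g$tag, rownames(v), as.numeric(v))
}

#' Dump feature groups as a data frame (for golden-file inspection)
#' @param groups list of feature groups.
#' @return Data frame with columns `group`, `name`, `value`, sorted.
#' @export
feature_dump <- function(groups) {
  rows <- lapply(groups, function(g) {
    g <- .fg_collapse(g)
    if (!length(g$names)) return(NULL)
    data.frame(group = g$tag, name = g$names, value = g$values,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(group = character(), name = character(), value = numeric()))
  }
  out <- out[order(out$group, out$name), ]
  rownames(out) <- NULL
  out
}

.char_ngrams <- function(s, orders) {
  nc <- nchar(s)
  out <- character()
  for (n in orders) {
    if (nc < n) next
    out <- c(out, substring(s, 1:(nc - n + 1L), n:nc))
  }
  out
}

#' Token features
#'
#' Character-type indicators, character n-grams of the surface form, the
#' lemma (base form) and the part-of-speech tag.
#'
#' @param surface,lemma,pos the token's surface string, base form and POS.
#' @param config a [feature_config()].
#' @param tag group tag (default `"token"`).
#' @return A feature group.
#' @export
token_features <- function(surface, lemma, pos, config = feature_config(),
                           tag = "token") {
  ct <- c("ct:has_digit", "ct:has_symbol", "ct:all_upper", "ct:init_cap",
          "ct:has_hyphen")[c(grepl("[0-9]", surface),
                             grepl("[^A-Za-z0-9]", surface),
                             grepl("^[A-Z]+$", surface),
                             grepl("^[A-Z]", surface),
                             grepl("-", surface, fixed = TRUE))]
  grams <- paste0("cg:", .char_ngrams(surface, config$char_ngrams))
  .fg(tag, c(ct, grams, paste0("lemma:", lemma), paste0("pos:", pos)))
}

# --- dependency graph helpers ------------------------------------------------

# adjacency list on the undirected view: for each token index, parallel
# vectors nbr (sorted), rel, nbr_is_head.  Computed once per sentence graph
# and passed down the hot paths.
.adjacency <- function(graph, n_tokens) {
  keep <- graph$head != 0L
  h <- graph$head[keep]; d <- graph$dep[keep]; rel <- graph$rel[keep]
  node <- c(d, h); nbr <- c(h, d); nbr_head <- c(rep(TRUE, length(h)), rep(FALSE, length(h)))
  erel <- c(rel, rel)
  o <- order(node, nbr)
  node <- node[o]; nbr <- nbr[o]; nbr_head <- nbr_head[o]; erel <- erel[o]
  adj <- vector("list", n_tokens)
  if (length(node)) {
    idx <- split(seq_along(node), factor(node, levels = seq_len(n_tokens)))
    for (i in seq_len(n_tokens)) {
      k <- idx[[i]]
      if (length(k)) adj[[i]] <- list(nbr = nbr[k], rel = erel[k],
                                      nbr_is_head = nbr_head[k])
    }
  }
  adj
}

# directed edge string between consecutive path words L, R
.edge_str <- function(rel, right_is_head) {
  ifelse(right_is_head, paste0(.DASH, rel, .ARROW_R), paste0(.ARROW_L, rel, .DASH))
}

# BFS shortest path on the undirected view; returns token index vector or
# NULL.  `adj` may be precomputed with .adjacency().
.shortest_path <- function(graph, n_tokens, from, to, adj = NULL) {
  if (from == to) return(from)
  if (is.null(adj)) adj <- .adjacency(graph, n_tokens)
  prev <- integer(n_tokens)
  seen <- logical(n_tokens)
  seen[from] <- TRUE
  frontier <- from
  while (length(frontier)) {
    nxt <- integer()
    for (u in frontier) {
      a <- adj[[u]]
      if (is.null(a)) next
      for (v in a$nbr) {              # nbr is sorted: deterministic expansion
        if (!seen[v]) {
          seen[v] <- TRUE; prev[v] <- u
          if (v == to) {
            path <- v
            while (path[1L] != from) path <- c(prev[path[1L]], path)
            return(path)
          }
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  NULL
}

# edge descriptors along a token-index path: rel + whether right node is head
.path_edges <- function(adj, path) {
  k <- length(path) - 1L
  if (k < 1L) return(NULL)
  rel <- character(k); right_head <- logical(k)
  for (m in seq_len(k)) {
    a <- adj[[path[m]]]
    j <- match(path[m + 1L], a$nbr)
    if (is.na(j)) stop("path edge not present in graph")
    rel[m] <- a$rel[j]; right_head[m] <- a$nbr_is_head[j]
  }
  list(rel = rel, right_head = right_head)
}

#' Render a dependency path as a human-readable string
#'
#' Words are surface forms; edges are rendered with arrows pointing at the
#' head (`A ←REL– B` when A governs B).
#'
#' @param path vector of token indices.
#' @param sentence the sentence holding the tokens.
#' @param graph an edge data frame of that sentence.
#' @return A single string, e.g.
#'   `"were ←PRD– unable ←AMOD– transactivate"`.
#' @export
path_string <- function(path, sentence, graph) {
  words <- sentence$tokens$surface[path]
  if (length(path) == 1L) return(words)
  adj <- .adjacency(graph, nrow(sentence$tokens))
  ed <- .path_edges(adj, path)
  out <- words[1L]
  for (m in seq_along(ed$rel)) {
    out <- paste(out, .edge_str(ed$rel[m], ed$right_head[m]), words[m + 1L])
  }
  out
}

# contiguous n-grams (joined by a space) of an element vector
.ngrams <- function(elems, orders, prefix) {
  L <- length(elems)
  out <- vector("list", length(orders))
  for (k in seq_along(orders)) {
    n <- orders[k]
    if (L < n) next
    m <- L - n + 1L
    parts <- elems[seq_len(m)]
    if (n > 1L) for (j in 2:n) parts <- paste(parts, elems[j:(j + m - 1L)])
    out[[k]] <- paste0(prefix, n, ":", parts)
  }
  unlist(out, use.names = FALSE)
}

# alternating word/edge element sequence for a path (words as lemmas)
.path_elems <- function(path, lemmas, edges) {
  elems <- lemmas[path[1L]]
  for (m in seq_along(edges$rel)) {
    elems <- c(elems, .edge_str(edges$rel[m], edges$right_head[m]), lemmas[path[m + 1L]])
  }
  elems
}

#' Neighbouring word features
#'
#' Extracts every dependency path of up to `neighbour_depth` (default 2)
#' steps from the target word and derives n-grams from it: token features of
#' each word on the path, mixed word+dependency n-grams (n = 2,3,4), word
#' n-grams (n = 2,3) and dependency n-grams (n = 2).  Paths are oriented so
#' that the target word comes last; words are lemmas.
#'
#' @param index target token row index within the sentence.
#' @param sentence a sentence with tokens.
#' @param graph an edge data frame of that sentence.
#' @param config a [feature_config()].
#' @param tag group tag (default `"neighbour"`).
#' @return A feature group (empty for an isolated token).
#' @export
neighbouring_word_features <- function(index, sentence, graph,
                                       config = feature_config(),
                                       tag = "neighbour", adj = NULL) {
  tok <- sentence$tokens
  if (is.null(adj)) adj <- .adjacency(graph, nrow(tok))
  lem <- tolower(tok$lemma)
  # enumerate simple paths target -> ... of length <= depth, then reverse
  paths <- list()
  walk <- function(path) {
    if (length(path) > 1L) paths[[length(paths) + 1L]] <<- rev(path)
    if (length(path) > config$neighbour_depth) return(invisible())
    a <- adj[[path[length(path)]]]
    if (is.null(a)) return(invisible())
    for (v in a$nbr) {
      if (!v %in% path) walk(c(path, v))
    }
  }
  walk(index)
  names_list <- vector("list", length(paths))
  seen_words <- integer()
  for (pi in seq_along(paths)) {
    p <- paths[[pi]]
    ed <- .path_edges(adj, p)
    elems <- .path_elems(p, lem, ed)
    words <- lem[p]
    edges <- .edge_str(ed$rel, ed$right_head)
    names_list[[pi]] <- c(.ngrams(elems, 2:4, "wd"),
                          .ngrams(words, 2:3, "w"),
                          .ngrams(edges, 2L, "d"))
    seen_words <- union(seen_words, p)
  }
  names_out <- unlist(names_list, use.names = FALSE)
  if (!length(paths)) return(.fg(tag, character()))
  tf <- lapply(sort(seen_words), function(i) {
    token_features(tok$surface[i], lem[i], tok$pos[i], config)$names
  })
  .fg(tag, c(unique(unlist(tf)), names_out))
}

.encode_window_word <- function(lemma, pos, mark) paste0(lemma, "/", pos, "/", mark)

#' Word n-gram features around a target word
#'
#' Word n-grams (n = 1..4) within a window of `window` words before and
#' after the target; each word is encoded as lemma/POS/relative-position
#' (`B` before, `T` target, `A` after).  The window truncates at sentence
#' boundaries.
#'
#' @inheritParams neighbouring_word_features
#' @param tag group tag (default `"word-ngram"`).
#' @return A feature group.
#' @export
word_ngram_features <- function(index, sentence, config = feature_config(),
                                tag = "word-ngram") {
  tok <- sentence$tokens
  lo <- max(1L, index - config$window)
  hi <- min(nrow(tok), index + config$window)
  idx <- lo:hi
  mark <- ifelse(idx < index, "B", ifelse(idx > index, "A", "T"))
  enc <- .encode_window_word(tolower(tok$lemma[idx]), tok$pos[idx], mark)
  .fg(tag, .ngrams(enc, 1:4, "n"))
}

#' Word window of a mention pair with before/between/after segmentation
#'
#' @param i,j token row indices of the two mentions.
#' @param sentence a sentence with tokens.
#' @param window words of context on each side (default 3).
#' @return List with surface-word vectors `before`, `between`, `after` and
#'   `window` (their concatenation).
#' @export
pair_window <- function(i, j, sentence, window = 3L) {
  tok <- sentence$tokens
  first <- min(i, j); last <- max(i, j)
  lo <- max(1L, first - window)
  hi <- min(nrow(tok), last + window)
  list(before = if (lo < first) tok$surface[lo:(first - 1L)] else character(),
       between = tok$surface[first:last],
       after = if (hi > last) tok$surface[(last + 1L):hi] else character(),
       window = tok$surface[lo:hi])
}

#' Pair n-gram features
#'
#' Word n-grams (n = 1..4) over the window from `window` words before the
#' first mention to `window` words after the last; each word is encoded as
#' lemma/POS/relative-position (`B` before, `M` between — inclusive of the
#' pair's own words — `A` after).
#'
#' @inheritParams pair_window
#' @param config a [feature_config()].
#' @param tag group tag (default `"pair-ngram"`).
#' @return A feature group.
#' @export
pair_ngram_features <- function(i, j, sentence, config = feature_config(),
                                tag = "pair-ngram") {
  tok <- sentence$tokens
  first <- min(i, j); last <- max(i, j)
  lo <- max(1L, first - config$window)
  hi <- min(nrow(tok), last + config$window)
  idx <- lo:hi
  mark <- ifelse(idx < first, "B", ifelse(idx > last, "A", "M"))
  enc <- .encode_window_word(tolower(tok$lemma[idx]), tok$pos[idx], mark)
  .fg(tag, .ngrams(enc, 1:4, "n"))
}

#' Shortest dependency path features
#'
#' Features of the (unique, in a tree) shortest undirected dependency path
#' between two tokens: path length, word n-grams (n = 2,3,4), dependency
#' n-grams (n = 2,3,4), consecutive governor-dependent word n-grams
#' (n = 1,2,3; e.g. `IEXC29S →be`, `be ←unable`), edge walks
#' (word-dependency-word) with their one-sided sub-structures, and vertex
#' walks (dependency-word-dependency) with their word-dropped
#' sub-structures.  Words are lemmas; original edge directions are retained
#' as arrows in the feature names.
#'
#' @param i,j token row indices of the endpoints.
#' @param sentence a sentence with tokens.
#' @param graph an edge data frame of that sentence.
#' @param config a [feature_config()].
#' @param tag group tag (default `"shortest-path"`).
#' @return A feature group.  Identical endpoints give `len:0` only; a
#'   disconnected pair gives a single `nopath` indicator.
#' @export
shortest_path_features <- function(i, j, sentence, graph,
                                   config = feature_config(),
                                   tag = "shortest-path", adj = NULL) {
  tok <- sentence$tokens
  lem <- tolower(tok$lemma)
  if (is.null(adj)) adj <- .adjacency(graph, nrow(tok))
  path <- .shortest_path(graph, nrow(tok), i, j, adj = adj)
  if (is.null(path)) return(.fg(tag, "nopath"))
  k <- length(path) - 1L
  out <- paste0("len:", k)
  if (k >= 1L) {
    ed <- .path_edges(adj, path)
    words <- lem[path]
    edges <- .edge_str(ed$rel, ed$right_head)
    # governor-dependent units for consecutive word pairs
    gd <- vapply(seq_len(k), function(m) {
      if (ed$right_head[m]) paste0(words[m], " ", .ARROW_R, words[m + 1L])
      else paste0(words[m], " ", .ARROW_L, words[m + 1L])
    }, character(1))
    # edge walks word-dep-word; direction glued to the relation label
    ew_rel <- vapply(seq_len(k), function(m) {
      if (ed$right_head[m]) paste0(ed$rel[m], .ARROW_R) else paste0(.ARROW_L, ed$rel[m])
    }, character(1))
    ew <- c(paste0("ew:", words[1:k], " ", ew_rel, " ", words[2:(k + 1L)]),
            paste0("ews:", words[1:k], " ", ew_rel),
            paste0("ews:", ew_rel, " ", words[2:(k + 1L)]))
    vw <- character()
    if (k >= 2L) {
      vw <- c(paste0("vw:", edges[1:(k - 1L)], " ", words[2:k], " ", edges[2:k]),
              paste0("vws:", edges[1:(k - 1L)], " ", edges[2:k]))
    }
    out <- c(out,
             .ngrams(words, 2:4, "w"),
             .ngrams(edges, 2:4, "d"),
             .ngrams(gd, 1:3, "gd"),
             ew, vw)
  }
  .fg(tag, out)
}

#' Sentence position features
#'
#' Absolute sentence index and relative position (index / sentence count)
#' within the document.
#'
#' @param sentence_index 1-based sentence index.
#' @param n_sentences number of sentences in the document.
#' @param tag group tag (default `"sentence"`).
#' @return A feature group with an `abs:<i>` indicator and a real-valued
#'   `rel` feature.
#' @export
sentence_position_features <- function(sentence_index, n_sentences,
                                       tag = "sentence") {
  .fg(tag, c(paste0("abs:", sentence_index), "rel"),
      c(1, sentence_index / n_sentences))
}

#' Cue path features
#'
#' Shortest dependency path features between each event participant head
#' token (trigger and arguments) and each matched cue mention's head token,
#' with every feature name prefixed by the cue entry's dimension and value
#' (a cue carrying several lexicon entries emits the same path under each
#' prefix).
#'
#' @param participants integer vector of participant head-token indices.
#' @param mentions cue mentions from [match_cues()].
#' @param sentence a sentence with tokens.
#' @param graph an edge data frame of that sentence.
#' @param config a [feature_config()].
#' @param tag group tag (default `"cue-path"`).
#' @return A feature group (empty when there are no mentions).
#' @export
cue_path_features <- function(participants, mentions, sentence, graph,
                              config = feature_config(), tag = "cue-path",
                              adj = NULL) {
  if (length(mentions) && is.null(adj)) {
    adj <- .adjacency(graph, nrow(sentence$tokens))
  }
  parts <- list()
  for (m in mentions) {
    cue_tok <- m$last_token
    pre <- paste0(m$entries$dimension, ":", m$entries$value, "|")
    for (p in participants) {
      spf <- shortest_path_features(p, cue_tok, sentence, graph, config, adj = adj)
      parts[[length(parts) + 1L]] <- paste0(rep(pre, each = length(spf$names)),
                                            spf$names)
    }
  }
  .fg(tag, unlist(parts, use.names = FALSE))
}

# --- hashing and normalisation ----------------------------------------------

.new_hashed_vector <- function(i, x, dim) {
  structure(list(i = as.integer(i), x = as.numeric(x), dim = as.integer(dim)),
            class = "hashed_vector")
}

#' @exportS3Method base::print
print.hashed_vector <- function(x, ...) {
  cat(sprintf("<hashed_vector: %d non-zeros in dimension %d, L2 = %.4g>\n",
              length(x$i), x$dim, sqrt(sum(x$x^2))))
  invisible(x)
}

# hash one group's (collapsed) names; returns data.frame(i, x), 1-based
.hash_group <- function(g, bits, scale = 1) {
  g <- .fg_collapse(g)
  if (!length(g$names)) return(NULL)
  idx <- .fnv1a_hash(paste0(g$tag, "\r", g$names), bits) + 1L
  data.frame(i = idx, x = g$values * scale)
}

#' Hash feature groups into a fixed sparse space
#'
#' Each named feature is mapped by a deterministic FNV-1a hash of
#' `group tag + name` into `[0, 2^hash_bits)`; features colliding on an
#' index sum.
#'
#' @param groups list of feature groups.
#' @param config a [feature_config()] (provides `hash_bits`; default gives a
#'   `2^20 = 1,048,576`-dimensional space).
#' @return A `hashed_vector` with 1-based sparse indices `i`, values `x` and
#'   the space dimension `dim`.
#' @export
hash_features <- function(groups, config = feature_config()) {
  bits <- config$hash_bits
  parts <- Filter(Negate(is.null), lapply(groups, .hash_group, bits = bits))
  if (!length(parts)) return(.new_hashed_vector(integer(), numeric(), 2^bits))
  df <- do.call(rbind, parts)
  v <- rowsum(df$x, df$i)
  .new_hashed_vector(as.integer(rownames(v)), as.numeric(v), 2^bits)
}

#' Type-based feature normalisation
#'
#' Scales each feature group to unit Euclidean (L2) length, hashes the
#' groups, then scales the concatenated hashed vector to unit L2 length.
#' All-zero groups and vectors pass through unchanged.
#'
#' @inheritParams hash_features
#' @return A `hashed_vector` of unit L2 norm (when non-zero).
#' @export
normalise_typewise <- function(groups, config = feature_config()) {
  bits <- config$hash_bits
  parts <- list()
  for (g in groups) {
    g <- .fg_collapse(g)
    if (!length(g$names)) next
    nrm <- sqrt(sum(g$values^2))
    parts[[length(parts) + 1L]] <- .hash_group(g, bits,
                                               scale = if (nrm > 0) 1 / nrm else 1)
  }
  if (!length(parts)) return(.new_hashed_vector(integer(), numeric(), 2^bits))
  df <- do.call(rbind, parts)
  v <- rowsum(df$x, df$i)
  x <- as.numeric(v)
  gn <- sqrt(sum(x^2))
  if (gn > 0) x <- x / gn
  .new_hashed_vector(as.integer(rownames(v)), x, 2^bits)
}

# stack hashed vectors into a sparse dgCMatrix (rows = instances)
.stack_hashed <- function(vectors) {
  dims <- unique(vapply(vectors, `[[`, integer(1), "dim"))
  stopifnot(length(dims) == 1L)
  i <- rep(seq_along(vectors), vapply(vectors, function(v) length(v$i), integer(1)))
  j <- unlist(lapply(vectors, `[[`, "i"), use.names = FALSE)
  x <- unlist(lapply(vectors, `[[`, "x"), use.names = FALSE)
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(vectors), dims))
}
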