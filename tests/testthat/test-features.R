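wd <- worked_doc()
ws <- wd$sentences[[1L]]
wg <- ws$graphs$gdep

test_that("token features cover character types, n-grams, lemma and POS", {
  g <- token_features("transactivate", "transactivate", "VB")
  expect_true(all(c("cg:t", "cg:r", "cg:tr", "cg:ra", "cg:tra", "cg:ran",
                    "cg:tran", "cg:rans") %in% g$names))
  g <- token_features("were", "be", "VBD")
  expect_true(all(c("lemma:be", "pos:VBD") %in% g$names))
  # one-character token: only unigrams
  g <- token_features("a", "a", "DT")
  expect_true("cg:a" %in% g$names)
  expect_false(any(grepl("^cg:..", g$names)))
  # character-type indicators
  g <- token_features("c-sis/PDGF-B", "c-sis/pdgf-b", "NN")
  expect_true(all(c("ct:has_symbol", "ct:has_hyphen") %in% g$names))
  expect_false("ct:all_upper" %in% g$names)
})

test_that("neighbouring word features extract 2-step path n-grams", {
  g <- neighbouring_word_features(6L, ws, wg)
  # the printed 2-step path pieces: be <-PRD- / <-PRD- unable <-AMOD-
  expect_true("wd2:be ←PRD–" %in% g$names)
  expect_true("wd3:←PRD– unable ←AMOD–" %in% g$names)
  expect_true(all(c("w2:be unable", "w2:unable transactivate",
                    "w3:be unable transactivate") %in% g$names))
  expect_true("d2:←PRD– ←AMOD–" %in% g$names)
  # token features of path words are included
  expect_true("lemma:unable" %in% g$names)
  # isolated token -> empty group
  tok <- data.frame(index = 1L, surface = "x", lemma = "x", pos = "NN",
                    stringsAsFactors = FALSE)
  s <- as_sentence(tok)
  g0 <- neighbouring_word_features(1L, s, data.frame(head = 0L, dep = 1L,
                                                     rel = "ROOT"))
  expect_length(g0$names, 0L)
})

test_that("word n-gram window is +/-3 words with positional encoding", {
  g <- word_ngram_features(6L, ws)
  # window = unable..promoter; unigram encodings carry B/T/A marks
  expect_true("n1:unable/JJ/B" %in% g$names)
  expect_true("n1:transactivate/VB/T" %in% g$names)
  expect_true("n1:promoter/NN/A" %in% g$names)
  expect_false(any(grepl("iexc29s", g$names)))  # outside the window
  # n-gram spanning the target mixes marks
  expect_true("n3:significantly/RB/B transactivate/VB/T the/DT/A" %in% g$names)
  # sentence-initial token: truncated window, only following words
  g1 <- word_ngram_features(1L, ws)
  expect_false(any(grepl("/A /", g1$names)))
  expect_true("n1:iexc29s/NN/T" %in% g1$names)
  expect_true("n1:unable/JJ/A" %in% g1$names)
  expect_false(any(grepl("/B$", g1$names)))
})

test_that("pair window segments before/between/after as printed", {
  pw <- pair_window(6L, 8L, ws)
  expect_equal(pw$before, c("unable", "to", "significantly"))
  expect_equal(pw$between, c("transactivate", "the", "c-sis/PDGF-B"))
  expect_equal(pw$after, "promoter")
  expect_equal(paste(pw$window, collapse = " "),
               "unable to significantly transactivate the c-sis/PDGF-B promoter")
  # adjacent pair: between only contains the pair's own words
  pw <- pair_window(2L, 3L, ws)
  expect_equal(pw$between, c("were", "unable"))
  # pair ending the sentence: empty after segment
  pw <- pair_window(8L, 9L, ws)
  expect_length(pw$after, 0L)

  g <- pair_ngram_features(6L, 8L, ws)
  expect_true("n1:unable/JJ/B" %in% g$names)
  expect_true("n1:the/DT/M" %in% g$names)
  expect_true("n1:promoter/NN/A" %in% g$names)
})

test_that("shortest path features reproduce the worked example", {
  path <- biomek:::.shortest_path(wg, 9L, 1L, 6L)
  expect_equal(path, c(1L, 2L, 3L, 6L))
  expect_equal(path_string(path, ws, wg),
               "IEXC29S –SUB→ were ←PRD– unable ←AMOD– transactivate")
  # the 2-step neighbourhood path of the trigger, rendered
  expect_equal(path_string(c(2L, 3L, 6L), ws, wg),
               "were ←PRD– unable ←AMOD– transactivate")
  g <- shortest_path_features(1L, 6L, ws, wg)
  expect_true("len:3" %in% g$names)
  # governor-dependent consecutive word units
  expect_true("gd1:iexc29s →be" %in% g$names)
  expect_true("gd1:be ←unable" %in% g$names)
  expect_true("gd2:iexc29s →be be ←unable" %in% g$names)
  # edge walks and sub-structures
  expect_true("ew:iexc29s SUB→ be" %in% g$names)
  expect_true("ews:iexc29s SUB→" %in% g$names)
  # vertex walks and word-dropped sub-structures
  expect_true("vw:–SUB→ be ←PRD–" %in% g$names)
  expect_true("vws:–SUB→ ←PRD–" %in% g$names)
  # identical endpoints: length 0, no walks
  g0 <- shortest_path_features(3L, 3L, ws, wg)
  expect_equal(g0$names, "len:0")
  # disconnected pair: no-path indicator
  tok <- data.frame(index = 1:2, surface = c("a", "b"), lemma = c("a", "b"),
                    pos = c("NN", "NN"), stringsAsFactors = FALSE)
  s2 <- as_sentence(tok)
  g2 <- shortest_path_features(1L, 2L, s2,
                               data.frame(head = c(0L, 0L), dep = 1:2,
                                          rel = c("ROOT", "ROOT")))
  expect_equal(g2$names, "nopath")
})

test_that("shortest paths agree with the igraph oracle on random trees", {
  skip_if_not_installed("igraph")
  set.seed(21)
  for (rep in 1:60) {
    n <- sample(2:10, 1L)
    gr <- random_tree(n)
    keep <- gr$head != 0L
    ig <- igraph::graph_from_edgelist(cbind(gr$head[keep], gr$dep[keep]),
                                      directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0L, n - igraph::vcount(ig)))
    pair <- sample.int(n, 2L)
    oracle <- as.integer(igraph::shortest_paths(ig, pair[1L], pair[2L])$vpath[[1L]])
    got <- biomek:::.shortest_path(gr, n, pair[1L], pair[2L])
    expect_equal(got, oracle)
  }
})

test_that("sentence position features are absolute + relative", {
  g <- sentence_position_features(2L, 8L)
  expect_true("abs:2" %in% g$names)
  expect_equal(g$values[g$names == "rel"], 0.25)
  g <- sentence_position_features(1L, 1L)
  expect_equal(g$values[g$names == "rel"], 1)
  g <- sentence_position_features(3L, 4L)
  expect_equal(g$values[g$names == "rel"], 0.75)
})

test_that("cue path features are emitted once per matching lexicon entry", {
  doc <- tiny_doc()
  s <- doc$sentences[[1L]]
  men <- match_cues(s, toy_lexicon())
  g <- cue_path_features(c(3L, 4L, 1L), men, s, s$graphs$gdep)
  # "may" carries a KT and a CL entry: same path under both prefixes
  kt <- grep("^KT:Analysis\\|", g$names, value = TRUE)
  cl <- grep("^CL:L1\\|", g$names, value = TRUE)
  expect_gt(length(kt), 0L)
  expect_equal(sort(sub("^KT:Analysis\\|", "", kt)),
               sort(sub("^CL:L1\\|", "", cl)))
  # no cues -> empty group
  expect_length(cue_path_features(c(3L), list(), s, s$graphs$gdep)$names, 0L)
})

test_that("feature extraction is deterministic across calls", {
  g1 <- feature_dump(list(neighbouring_word_features(6L, ws, wg),
                          shortest_path_features(1L, 6L, ws, wg)))
  g2 <- feature_dump(list(neighbouring_word_features(6L, ws, wg),
                          shortest_path_features(1L, 6L, ws, wg)))
  expect_identical(g1, g2)
})

test_that("hashing maps into [0, 2^bits) deterministically and sums collisions", {
  cfg <- feature_config()
  expect_equal(hash_features(list(), cfg)$dim, 2^20)
  g <- token_features("transactivate", "transactivate", "VB")
  h1 <- hash_features(list(g), cfg)
  h2 <- hash_features(list(g), cfg)
  expect_identical(h1, h2)
  expect_true(all(h1$i >= 1L & h1$i <= 2^20))

  # construct a collision at 4 bits and verify additivity
  idx <- biomek:::.fnv1a_hash(paste0("t\r", sprintf("n%03d", 1:200)), 4L)
  dup <- which(idx == idx[1L])
  expect_gt(length(dup), 1L)
  small <- feature_config(hash_bits = 4L)
  gg <- biomek:::.fg("t", sprintf("n%03d", dup[1:2]), c(2, 5))
  h <- hash_features(list(gg), small)
  expect_equal(h$x[h$i == idx[1L] + 1L], 7)
})

test_that("type-based normalisation gives unit group and global norms", {
  cfg <- feature_config(hash_bits = 16L)
  g <- biomek:::.fg("t", c("a", "b"), c(3, 4))
  v <- normalise_typewise(list(g), cfg)
  expect_equal(sort(v$x), c(0.6, 0.8))
  # two groups: each contributes unit mass pre-global scaling; global norm 1
  g2 <- biomek:::.fg("u", c("c", "d", "e"), c(1, 2, 2))
  v <- normalise_typewise(list(g, g2), cfg)
  expect_equal(sqrt(sum(v$x^2)), 1)
  # all-zero input: all-zero output, no division error
  v0 <- normalise_typewise(list(biomek:::.fg("t", character())), cfg)
  expect_length(v0$x, 0L)
})
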