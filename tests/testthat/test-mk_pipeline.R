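# A small shared corpus + trained bundle keeps the per-block cost down.
pipe_docs <- generate_corpus(synth_config(n_docs = 36L, seed = 17L))
pipe_lex <- build_cue_lexicon(pipe_docs)
pipe_train <- pipe_docs[1:28]
pipe_test <- pipe_docs[29:36]
pipe_fc <- feature_config(hash_bits = 16L)
suppressWarnings(pipe_bundle <- train_mk(pipe_train, pipe_lex, config = pipe_fc))

test_that("hyper-dimensions derive from KT, CL and Source", {
  expect_equal(derive_hyperdimensions(mk_record(KT = "Investigation"))[["Hypothesis"]],
               "Yes")
  expect_equal(derive_hyperdimensions(mk_record(KT = "Analysis", CL = "L1"))[["Hypothesis"]],
               "Yes")
  expect_equal(derive_hyperdimensions(mk_record(KT = "Analysis", CL = "L3"))[["Hypothesis"]],
               "No")
  expect_equal(derive_hyperdimensions(mk_record(KT = "Fact"))[["NewKnowledge"]], "No")
  expect_equal(derive_hyperdimensions(mk_record(KT = "Observation"))[["NewKnowledge"]],
               "Yes")
  expect_equal(derive_hyperdimensions(mk_record(KT = "Observation", Source = "Other"))[["NewKnowledge"]],
               "No")
  # rule tables are configurable
  res <- derive_hyperdimensions(mk_record(), rules = list(
    hypothesis = function(m) TRUE))
  expect_equal(res[["Hypothesis"]], "Yes")
})

test_that("extract_mk_instance assembles the documented feature groups", {
  doc <- tiny_doc()
  inst <- extract_mk_instance("E1", doc, toy_lexicon(), feature_config(hash_bits = 14L))
  tags <- vapply(inst$groups, `[[`, character(1), "tag")
  expect_true("cue-path@gdep" %in% tags)
  expect_true("trigger@gdep" %in% tags)
  expect_true(all(c("pair", "sentence", "citation") %in% tags))
  # the sentence has a citation "[ 12 ]"
  cit <- inst$groups[[which(tags == "citation")]]
  expect_equal(cit$names, "has_citation")
  # cue-path features carry the matched "may" entries
  cp <- inst$groups[[which(tags == "cue-path@gdep")]]
  expect_true(any(startsWith(cp$names, "KT:Analysis|")))
  expect_true(any(startsWith(cp$names, "CL:L1|")))
  # pair features are computed per role
  pg <- inst$groups[[which(tags == "pair")]]
  expect_true(any(startsWith(pg$names, "Theme|")))
  expect_true(any(startsWith(pg$names, "Cause|")))
  expect_equal(sqrt(sum(inst$vector$x^2)), 1)

  # no cues, single-sentence doc, no citation: cue-path and citation empty
  wd <- worked_doc()
  inst <- extract_mk_instance("E1", wd, toy_lexicon(), feature_config(hash_bits = 14L))
  tags <- vapply(inst$groups, `[[`, character(1), "tag")
  expect_length(inst$groups[[which(tags == "citation")]]$names, 0L)
  expect_length(inst$groups[[which(tags == "cue-path@gdep")]]$names, 0L)
  expect_gt(length(inst$groups[[which(tags == "trigger@gdep")]]$names), 0L)

  expect_error(extract_mk_instance("E99", wd, toy_lexicon()), "no event")
})

test_that("nested argument events contribute their trigger token to pair features", {
  nested <- Filter(function(d) {
    any(vapply(d$events, function(ev)
      any(vapply(ev$args, function(a) startsWith(a$ref, "E"), logical(1))),
      logical(1)))
  }, pipe_docs)
  expect_gt(length(nested), 0L)
  doc <- nested[[1L]]
  ev <- Filter(function(ev) any(vapply(ev$args, function(a)
    startsWith(a$ref, "E"), logical(1))), doc$events)[[1L]]
  inst <- extract_mk_instance(ev$id, doc, pipe_lex, pipe_fc)
  tags <- vapply(inst$groups, `[[`, character(1), "tag")
  pg <- inst$groups[[which(tags == "pair")]]
  # the Theme argument is an event; its trigger lemma ("expression") shows up
  expect_true(any(grepl("^Theme\\|", pg$names) & grepl("expression", pg$names)))
})

test_that("assignment is total, deterministic and checksum-guarded", {
  blank <- lapply(pipe_test, function(d) { d$mk <- list(); d })
  res1 <- assign_metaknowledge(blank, pipe_bundle)
  res2 <- assign_metaknowledge(blank, pipe_bundle)
  for (id in names(res1$docs)) {
    doc <- res1$docs[[id]]
    expect_equal(length(doc$mk), length(doc$events))     # totality
    for (rec in doc$mk) {
      for (d in mk_dimensions()) expect_true(rec[[d]] %in% mk_scheme()[[d]])
      expect_false(is.null(attr(rec, "hyper")))
    }
  }
  expect_identical(res1$docs, res2$docs)                  # determinism
  expect_s3_class(res1$cues, "data.frame")
  # mismatched lexicon is a hard error
  other_lex <- build_cue_lexicon(pipe_docs, tau = 1)
  expect_error(assign_metaknowledge(blank, pipe_bundle, lexicon = other_lex),
               "checksum mismatch")
})

test_that("a default-dominated no-cue corpus predicts the scheme defaults", {
  dist0 <- list(KT = c(Other = 1, Investigation = 0, Observation = 0,
                       Analysis = 0, Fact = 0, Method = 0),
                CL = c(L3 = 1, L2 = 0, L1 = 0),
                Polarity = c(Positive = 1, Negative = 0),
                Manner = c(Neutral = 1, High = 0, Low = 0),
                Source = c(Current = 1, Other = 0))
  cfg <- synth_config(n_docs = 10L, value_dist = dist0, seed = 23L,
                      kt_position_bias = 0)
  docs0 <- generate_corpus(cfg)
  suppressWarnings(b0 <- train_mk(docs0[1:8], build_cue_lexicon(docs0),
                                  config = feature_config(hash_bits = 14L)))
  res <- assign_metaknowledge(lapply(docs0[9:10], function(d) { d$mk <- list(); d }),
                              b0)
  for (doc in res$docs) {
    for (rec in doc$mk) {
      expect_equal(vapply(mk_dimensions(), function(d) rec[[d]], character(1)),
                   unname(mk_defaults()), ignore_attr = TRUE)
    }
  }
})

test_that("stacked auxiliary scores add one feature per (dimension, value)", {
  doc <- pipe_test[[1L]]
  ev_id <- names(doc$events)[1L]
  inst <- extract_mk_instance(ev_id, doc, pipe_lex, pipe_fc)
  g <- stack_scores(inst$vector, pipe_bundle)
  expect_equal(g$tag, "stacked-score")
  expect_length(g$names, 16L)  # 6 KT + 3 CL + 2 Polarity + 3 Manner + 2 Source
  expect_setequal(
    g$names,
    unlist(lapply(mk_dimensions(), function(d) paste0(d, ":", mk_scheme()[[d]]))))
  expect_true(all(is.finite(g$values)))
  # no auxiliary model -> empty group, pipeline unchanged
  expect_length(stack_scores(inst$vector, NULL)$names, 0L)
  inst_plain <- extract_mk_instance(ev_id, doc, pipe_lex, pipe_fc, aux = NULL)
  expect_identical(inst$vector, inst_plain$vector)
})

test_that("training with stacked features uses them at prediction time", {
  suppressWarnings(stacked <- train_mk(pipe_train[1:10], pipe_lex, config = pipe_fc,
                                       aux = pipe_bundle))
  expect_true(stacked$stacked)
  blank <- lapply(pipe_test[1:2], function(d) { d$mk <- list(); d })
  expect_error(assign_metaknowledge(blank, stacked), "supply `aux`")
  res <- assign_metaknowledge(blank, stacked, aux = pipe_bundle)
  expect_equal(length(res$docs[[1L]]$mk), length(res$docs[[1L]]$events))
})

test_that("feature ablation switches drop the corresponding groups", {
  doc <- pipe_test[[1L]]
  ev_id <- names(doc$events)[1L]
  inst <- extract_mk_instance(ev_id, doc, pipe_lex, pipe_fc,
                              disable = c("cue-path", "citation"))
  tags <- vapply(inst$groups, `[[`, character(1), "tag")
  expect_false(any(startsWith(tags, "cue-path")))
  expect_false("citation" %in% tags)
  expect_true(any(startsWith(tags, "trigger")))
})

test_that("annotation transfer is exact, conservative, and reported", {
  pair <- generate_idmapped_pair(synth_config(n_docs = 6L, seed = 41L))
  res <- transfer_annotations(pair$source, pair$target, pair$id_map)
  expect_equal(res$report$transferred, res$report$total)   # perturbation 0
  # field-for-field equality with the source record
  for (r in seq_len(nrow(pair$id_map))) {
    m <- pair$id_map[r, ]
    expect_identical(res$docs[[m$doc_id]]$mk[[m$target_id]],
                     pair$source[[m$doc_id]]$mk[[m$source_id]])
  }

  pair2 <- generate_idmapped_pair(synth_config(n_docs = 12L, seed = 43L),
                                  perturb_fraction = 0.25)
  res2 <- transfer_annotations(pair2$source, pair2$target, pair2$id_map)
  expect_lt(res2$report$transferred, res2$report$total)
  expect_gt(res2$report$transferred, 0L)
  skipped <- res2$report$detail[res2$report$detail$outcome != "transferred", ]
  for (r in seq_len(nrow(skipped))) {
    expect_null(res2$docs[[skipped$doc_id[r]]]$mk[[skipped$target_id[r]]])
  }
  # deterministic given the seed
  pair2b <- generate_idmapped_pair(synth_config(n_docs = 12L, seed = 43L),
                                   perturb_fraction = 0.25)
  res2b <- transfer_annotations(pair2b$source, pair2b$target, pair2b$id_map)
  expect_equal(res2b$report$transferred, res2$report$transferred)

  # disjoint documents: nothing transferred, no error
  res3 <- transfer_annotations(pair$source[1:2], pair$target[3:4], pair$id_map)
  expect_equal(res3$report$transferred, 0L)
})

test_that("held-out quality degrades monotonically with label noise", {
  # scaled down relative to the acceptance-scale experiment (same design,
  # fewer documents and a smaller hashed space) to stay inside the test budget
  mean_macro_f <- function(noise) {
    docs <- generate_corpus(synth_config(n_docs = 120L, seed = 67L,
                                         label_noise = noise))
    lex <- build_cue_lexicon(docs)
    ntr <- 96L
    suppressWarnings(b <- train_mk(docs[1:ntr], lex,
                                   config = feature_config(hash_bits = 16L)))
    blank <- lapply(docs[(ntr + 1):120], function(d) { d$mk <- list(); d })
    res <- assign_metaknowledge(blank, b)
    evl <- evaluate_corpus(docs[(ntr + 1):120], res$docs)
    mean(vapply(evl, function(e) e$macro[["F"]], numeric(1)))
  }
  f <- vapply(c(0, 0.15, 0.4), mean_macro_f, numeric(1))
  expect_true(all(diff(f) < 0), label = paste("macro F by noise:",
                                              paste(round(f, 1), collapse = " > ")))
})

test_that("the learned cue detector recovers injected cues", {
  det <- suppressWarnings(train_cue_detector(pipe_train[1:12], pipe_lex,
                                             config = feature_config(hash_bits = 14L)))
  hits <- 0L; truths <- 0L
  for (doc in pipe_test[1:3]) {
    gold_cues <- Filter(function(tb) grepl("-cue$", tb$kind), doc$textbounds)
    truths <- truths + length(gold_cues)
    for (k in seq_along(doc$sentences)) {
      men <- detect_cues_learned(doc, k, det, pipe_lex)
      for (m in men) {
        match <- any(vapply(gold_cues, function(tb)
          tb$span[1L] == m$span[1L] && tb$span[2L] == m$span[2L], logical(1)))
        if (match) hits <- hits + 1L
      }
    }
  }
  expect_gt(truths, 0L)
  expect_gt(hits / truths, 0.8)
  # dictionary filter: tokens outside the dictionary are never candidates
  doc <- pipe_test[[1L]]
  men <- detect_cues_learned(doc, 1L, det, pipe_lex, dictionary_filter = TRUE)
  dict_words <- unique(unlist(strsplit(unique(pipe_lex$word), " ")))
  for (m in men) expect_true(m$word %in% dict_words)
})
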