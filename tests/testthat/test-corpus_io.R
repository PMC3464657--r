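test_that("standoff entity, event and attribute lines are parsed and resolved", {
  doc <- tiny_doc()
  expect_s3_class(doc, "mk_document")
  tb <- doc$textbounds$T1
  expect_equal(tb$kind, "Protein")
  expect_equal(tb$span, c(0L, 3L))
  expect_equal(tb$surface, "p53")
  expect_equal(tb$layer, "a1")

  e1 <- doc$events$E1
  expect_equal(e1$type, "Negative_regulation")
  expect_equal(e1$trigger, "T4")
  expect_equal(lapply(e1$args, `[[`, "role"), list("Theme", "Cause"))

  # nested event: E2 takes E1 as Theme and has no trigger
  e2 <- doc$events$E2
  expect_true(is.na(e2$trigger))
  expect_equal(e2$args[[1L]]$ref, "E1")

  expect_equal(unclass(doc$mk$E1)[["CL"]], "L1")
  expect_equal(doc$cue_links$tb_id, "T5")
  expect_silent(validate_document(doc))
})

test_that("malformed annotations are rejected with informative errors", {
  dir <- tiny_dir()
  # offset out of range
  writeLines("T9\tProtein 50 99\tnope", file.path(dir, "BAD.a1"))
  writeChar("short text", file.path(dir, "BAD.txt"), eos = NULL)
  expect_error(read_standoff(file.path(dir, "BAD.txt"), file.path(dir, "BAD.a1"),
                             file.path(dir, "nonexistent.a2")),
               "offset out of range")
  # surface mismatch
  writeLines("T9\tProtein 0 5\twrong", file.path(dir, "BAD.a1"))
  expect_error(read_standoff(file.path(dir, "BAD.txt"), file.path(dir, "BAD.a1"),
                             file.path(dir, "nonexistent.a2")),
               "surface mismatch")
  # dangling reference
  writeChar("p53 x", file.path(dir, "DANG.txt"), eos = NULL)
  writeLines("T1\tProtein 0 3\tp53", file.path(dir, "DANG.a1"))
  writeLines(c("T2\tBinding 4 5\tx", "E1\tBinding:T2 Theme:T7"),
             file.path(dir, "DANG.a2"))
  expect_error(read_standoff(file.path(dir, "DANG.txt"), file.path(dir, "DANG.a1"),
                             file.path(dir, "DANG.a2")),
               "unresolved reference")
})

test_that("parse reading aligns tokens to text and flags mismatches", {
  doc <- tiny_doc()
  s1 <- doc$sentences[[1L]]
  expect_equal(s1$tokens$surface[2L], "may")
  expect_equal(s1$tokens$start[2L], 4L)
  expect_equal(s1$tokens$end[2L], 7L)
  # lemma/POS carried through (CoNLL conventions)
  expect_equal(doc$sentences[[2L]]$tokens$lemma[2L], "be")
  expect_equal(doc$sentences[[2L]]$tokens$pos[2L], "VBD")
  # HEAD = 0 marks the root: exactly one root edge per sentence here
  expect_equal(sum(s1$graphs$gdep$head == 0L), 1L)

  dir <- tiny_dir()
  bad <- readLines(file.path(dir, "TINY.conll"))
  bad[2L] <- "1\tp54\tp54\tNN\t3\tSUB"   # token/text mismatch
  writeLines(bad, file.path(dir, "TINY.conll"))
  base <- read_standoff(file.path(dir, "TINY.txt"), file.path(dir, "TINY.a1"),
                        file.path(dir, "TINY.a2"))
  expect_error(read_parse(file.path(dir, "TINY.conll"), base),
               "alignment error.*offset 0")
})

test_that("discontinuous spans resolve to the smallest covering span", {
  expect_equal(resolve_discontinuous_span(list(c(10L, 15L), c(20L, 26L))),
               c(10L, 26L))
  expect_equal(resolve_discontinuous_span(list(c(5L, 9L))), c(5L, 9L))
  expect_equal(resolve_discontinuous_span(list(c(30L, 34L), c(12L, 18L))),
               c(12L, 34L))
  expect_error(resolve_discontinuous_span(list()), "empty")
  # property: output contains every fragment and no smaller span does
  set.seed(4)
  for (rep in 1:25) {
    frags <- lapply(seq_len(sample(1:5, 1L)), function(i) {
      s <- sample(0:80, 1L); c(s, s + sample(1:10, 1L))
    })
    sp <- resolve_discontinuous_span(frags)
    expect_true(all(vapply(frags, function(f) sp[1L] <= f[1L] && f[2L] <= sp[2L],
                           logical(1))))
    expect_equal(sp[1L], min(vapply(frags, `[`, numeric(1), 1L)))
    expect_equal(sp[2L], max(vapply(frags, `[`, numeric(1), 2L)))
  }
})

test_that("discontinuous text-bounds round-trip through standoff files", {
  dir <- tempfile(); dir.create(dir)
  writeChar("abc def ghi", file.path(dir, "D.txt"), eos = NULL)
  writeLines("T1\tProtein 0 3;8 11\tabc ghi", file.path(dir, "D.a1"))
  writeLines(character(), file.path(dir, "D.a2"))
  doc <- read_standoff(file.path(dir, "D.txt"), file.path(dir, "D.a1"),
                       file.path(dir, "D.a2"))
  expect_equal(doc$textbounds$T1$span, c(0L, 11L))  # smallest covering span
  expect_equal(length(doc$textbounds$T1$fragments), 2L)
  out <- tempfile(); dir.create(out)
  write_standoff(doc, out)
  expect_identical(readLines(file.path(out, "D.a1")),
                   "T1\tProtein 0 3;8 11\tabc ghi")
})

test_that("trigger-less events are removed transitively", {
  doc <- tiny_doc()
  expect_length(doc$events, 2L)
  expect_message(filtered <- filter_triggerless_events(doc), "removed 1")
  expect_named(filtered$events, "E1")
  expect_equal(attr(filtered, "removed_events"), 1L)
  expect_silent(validate_document(filtered))

  # a parent whose argument event is removed goes too
  dir <- tempfile(); dir.create(dir)
  writeChar("a b c", file.path(dir, "N.txt"), eos = NULL)
  writeLines(c("T1\tProtein 0 1\ta"), file.path(dir, "N.a1"))
  writeLines(c("T2\tPositive_regulation 2 3\tb",
               "E1\tGene_expression Theme:T1",            # trigger-less
               "E2\tPositive_regulation:T2 Theme:E1",     # depends on E1
               "E3\tPositive_regulation:T2 Theme:E2"),    # depends on E2
             file.path(dir, "N.a2"))
  doc <- read_standoff(file.path(dir, "N.txt"), file.path(dir, "N.a1"),
                       file.path(dir, "N.a2"))
  expect_message(filtered <- filter_triggerless_events(doc), "removed 3")
  expect_length(filtered$events, 0L)
  # document whose events all have triggers is unchanged
  wd <- worked_doc()
  expect_equal(filter_triggerless_events(wd)$events, wd$events)
})

test_that("write -> read round-trips documents field-for-field", {
  docs <- generate_corpus(synth_config(n_docs = 4L, seed = 9L))
  dir <- tempfile(); dir.create(dir)
  write_corpus(docs, dir)
  back <- read_corpus(dir)
  expect_equal(back, docs, ignore_attr = FALSE)
  # attribute lines: 5 per event carrying meta-knowledge
  id <- names(docs)[1L]
  a2 <- readLines(file.path(dir, paste0(id, ".a2")))
  expect_equal(sum(startsWith(a2, "A")), 5L * length(docs[[id]]$events))
})

test_that("an empty document writes valid, re-readable files", {
  doc <- structure(list(doc_id = "EMPTY", text = "nothing here",
                        textbounds = list(), events = list(), mk = list(),
                        cue_links = data.frame(event_id = character(),
                                               dimension = character(),
                                               tb_id = character(),
                                               stringsAsFactors = FALSE),
                        sentences = list()),
                   class = "mk_document")
  dir <- tempfile(); dir.create(dir)
  write_standoff(doc, dir)
  back <- read_corpus(dir)[[1L]]
  expect_length(back$events, 0L)
  expect_length(back$textbounds, 0L)
  expect_silent(validate_document(back))
})
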