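# Fixtures built in code (no binary data).  The "worked example" document
# reproduces the classic shortest-dependency-path sentence: a mutant protein
# that fails to transactivate a promoter, parsed GDep-style.

# token table + tree of the worked-example sentence
worked_tokens <- function() {
  data.frame(
    index = 1:9,
    surface = c("IEXC29S", "were", "unable", "to", "significantly",
                "transactivate", "the", "c-sis/PDGF-B", "promoter"),
    lemma = c("iexc29s", "be", "unable", "to", "significantly",
              "transactivate", "the", "c-sis/pdgf-b", "promoter"),
    pos = c("NN", "VBD", "JJ", "TO", "RB", "VB", "DT", "NN", "NN"),
    stringsAsFactors = FALSE)
}

worked_edges <- function() {
  data.frame(
    head = c(2L, 0L, 2L, 6L, 6L, 3L, 9L, 9L, 6L),
    dep = 1:9,
    rel = c("SUB", "ROOT", "PRD", "VMOD", "VMOD", "AMOD", "NMOD", "NMOD", "OBJ"),
    stringsAsFactors = FALSE)
}

# standoff + conll files for the worked example, written to a temp dir;
# returns the directory
worked_dir <- function() {
  tok <- worked_tokens()
  text <- paste(tok$surface, collapse = " ")
  starts <- c(0L, head(cumsum(nchar(tok$surface) + 1L), -1L))
  ends <- starts + nchar(tok$surface)
  dir <- tempfile("worked")
  dir.create(dir)
  writeChar(text, file.path(dir, "FIG4.txt"), eos = NULL)
  writeLines(sprintf("T1\tProtein %d %d\t%s", starts[1L], ends[1L], tok$surface[1L]),
             file.path(dir, "FIG4.a1"))
  ed <- worked_edges()
  writeLines(c(
    sprintf("T2\tPositive_regulation %d %d\t%s", starts[6L], ends[6L], tok$surface[6L]),
    sprintf("T3\tProtein %d %d\t%s", starts[8L], ends[8L], tok$surface[8L]),
    "E1\tPositive_regulation:T2 Theme:T3 Cause:T1"),
    file.path(dir, "FIG4.a2"))
  writeLines(c(sprintf("# sent 1 0 %d gdep", nchar(text)),
               sprintf("%d\t%s\t%s\t%s\t%d\t%s", tok$index, tok$surface,
                       tok$lemma, tok$pos, ed$head, ed$rel),
               ""),
             file.path(dir, "FIG4.conll"))
  dir
}

worked_doc <- function() {
  read_corpus(worked_dir())[[1L]]
}

# minimal two-sentence document built directly from standoff text, with a
# nested event, a trigger-less event, a cue and a citation
tiny_dir <- function() {
  dir <- tempfile("tiny")
  dir.create(dir)
  #        0         1         2         3         4         5
  #        0123456789012345678901234567890123456789012345678901234
  text <- "p53 may repress MDM2 [ 12 ] . TNF-alpha was reported ."
  writeChar(text, file.path(dir, "TINY.txt"), eos = NULL)
  writeLines(c("T1\tProtein 0 3\tp53",
               "T2\tProtein 16 20\tMDM2",
               "T3\tProtein 30 39\tTNF-alpha"),
             file.path(dir, "TINY.a1"))
  writeLines(c("T4\tNegative_regulation 8 15\trepress",
               "T5\tCL-cue 4 7\tmay",
               "E1\tNegative_regulation:T4 Theme:T2 Cause:T1",
               "E2\tPositive_regulation Theme:E1",
               "A1\tKT E1 Analysis",
               "A2\tCL E1 L1",
               "A3\tPolarity E1 Positive",
               "A4\tManner E1 Neutral",
               "A5\tSource E1 Current",
               "#1\tCueLink E1 CL T5"),
             file.path(dir, "TINY.a2"))
  writeLines(c("# sent 1 0 29 gdep",
               "1\tp53\tp53\tNN\t3\tSUB",
               "2\tmay\tmay\tMD\t3\tVMOD",
               "3\trepress\trepress\tVB\t0\tROOT",
               "4\tMDM2\tmdm2\tNN\t3\tOBJ",
               "5\t[\t[\t(\t3\tP",
               "6\t12\t12\tCD\t3\tP",
               "7\t]\t]\t)\t3\tP",
               "8\t.\t.\t.\t3\tP",
               "",
               "# sent 2 30 54 gdep",
               "1\tTNF-alpha\ttnf-alpha\tNN\t3\tSUB",
               "2\twas\tbe\tVBD\t3\tVMOD",
               "3\treported\treport\tVBD\t0\tROOT",
               "4\t.\t.\t.\t3\tP",
               ""),
             file.path(dir, "TINY.conll"))
  dir
}

tiny_doc <- function() read_corpus(tiny_dir())[[1L]]

# small cue lexicon built by hand
toy_lexicon <- function() {
  df <- data.frame(
    word = c("may", "may", "not", "previously"),
    dimension = c("KT", "CL", "Polarity", "Source"),
    value = c("Analysis", "L1", "Negative", "Other"),
    pmi = c(2.0, 2.5, 3.0, 3.0),
    stringsAsFactors = FALSE)
  biomek:::.new_cue_lexicon(df, tau = -1.5, base = 2)
}

# random labelled dependency tree on n tokens (for oracle tests)
random_tree <- function(n, rels = c("SUB", "OBJ", "NMOD", "VMOD", "PRD")) {
  head <- integer(n)
  if (n > 1L) for (i in 2:n) head[i] <- sample.int(i - 1L, 1L)
  data.frame(head = head, dep = seq_len(n),
             rel = c("ROOT", sample(rels, n - 1L, replace = TRUE))[seq_len(n)],
             stringsAsFactors = FALSE)
}

# sentence wrapper around bare token/edge tables
as_sentence <- function(tokens, span_start = 0L) {
  starts <- span_start + c(0L, head(cumsum(nchar(tokens$surface) + 1L), -1L))
  tokens$start <- starts
  tokens$end <- starts + nchar(tokens$surface)
  list(index = 1L, span = c(tokens$start[1L], tokens$end[nrow(tokens)]),
       tokens = tokens, graphs = list())
}
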