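test_that("tokenizer splits letter/digit runs and isolates punctuation", {
  expect_identical(nrow(tokenize("")), 0L)
  t1 <- tokenize("Sin dolor toráxico agudo.")
  expect_identical(t1$text, c("Sin", "dolor", "toráxico", "agudo", "."))
  t2 <- tokenize("(si en tiempo, no en espacio)")
  expect_identical(t2$text,
                   c("(", "si", "en", "tiempo", ",", "no", "en",
                     "espacio", ")"))
  # offsets recover the exact substrings and reconstruct the sentence
  for (txt in c("Sin dolor toráxico agudo.", "  a  b.c , d ",
                "pH 7.4; Na+ 140")) {
    tk <- tokenize(txt)
    expect_identical(substring(txt, tk$char_start + 1L, tk$char_end),
                     tk$text)
    rebuilt <- txt
    for (i in seq_len(nrow(tk)))
      rebuilt <- paste0(substr(rebuilt, 1, tk$char_start[i]),
                        tk$text[i],
                        substring(rebuilt, tk$char_end[i] + 1L))
    expect_identical(rebuilt, txt)
  }
})

test_that("standoff parser handles entities, fragments, links and errors", {
  expect_identical(parse_standoff("", "doc"),
                   list(cues = list(), scopes = list()))
  doc <- "Con no dolor"
  r <- parse_standoff("T1\tNegCue 4 6\tno", doc)
  expect_length(r$cues, 1)
  expect_identical(r$cues[[1]]$fragments,
                   data.frame(char_start = 4L, char_end = 6L))
  expect_identical(r$cues[[1]]$surface, "no")
  # ";" denotes discontinuous spans -> multi-fragment record
  r2 <- parse_standoff(
    c("T1\tNegCue 4 6\tno",
      "T2\tNegScope 0 3;7 12\tCon dolor",
      "R1\tScope Arg1:T1 Arg2:T2"), doc)
  expect_identical(nrow(r2$scopes[[1]]$fragments), 2L)
  expect_identical(r2$scopes[[1]]$cue_id, "T1")
  # offsets outside the document, surface mismatches, unknown types
  expect_error(parse_standoff("T1\tNegCue 4 99\tno", doc), "outside")
  expect_error(parse_standoff("T1\tNegCue 4 6\tsin", doc), "mismatch")
  expect_error(parse_standoff("T1\tMystery 4 6\tno", doc, "generic"),
               "unknown entity type")
  lenient <- parse_standoff("T1\tMystery 4 6\tno", doc, "nubes")
  expect_length(lenient$cues, 0)
  # cue-class attribute lines
  r3 <- parse_standoff(c("T1\tNegCue 4 6\tno", "A1\tCueClass T1 syntactic"),
                       doc)
  expect_identical(r3$cues[[1]]$cue_class, "syntactic")
})

test_that("document loading segments, re-bases and preserves annotations", {
  dir <- withr::local_tempdir()
  writeLines("No fiebre. No tos.", file.path(dir, "d1.txt"))
  writeLines(c("T1\tNegCue 0 2\tNo", "T2\tNegCue 11 13\tNo"),
             file.path(dir, "d1.ann"))
  corpus <- load_corpus(dir, dialect = "generic")
  expect_length(corpus, 2)
  expect_identical(corpus[[1]]$text, "No fiebre.")
  expect_identical(corpus[[2]]$text, "No tos.")
  # offsets re-based so each cue starts at 0
  expect_identical(corpus[[1]]$cues[[1]]$fragments$char_start, 0L)
  expect_identical(corpus[[2]]$cues[[1]]$fragments$char_start, 0L)
  # no .ann -> sentence without annotations
  dir2 <- withr::local_tempdir()
  writeLines("Paciente estable.", file.path(dir2, "d2.txt"))
  c2 <- load_corpus(dir2)
  expect_length(c2, 1)
  expect_length(c2[[1]]$cues, 0)
})

test_that("annotations crossing a sentence boundary merge the sentences", {
  dir <- withr::local_tempdir()
  writeLines("Sin tos. Estable ahora.", file.path(dir, "d.txt"))
  # scope spans the boundary between the two sentences
  writeLines(c("T1\tNegCue 0 3\tSin",
               "T2\tNegScope 4 16\ttos. Estable",
               "R1\tScope Arg1:T1 Arg2:T2"),
             file.path(dir, "d.ann"))
  expect_warning(corpus <- load_corpus(dir), "merging")
  expect_length(corpus, 1)
  expect_length(corpus[[1]]$scopes, 1)
})

test_that("standoff write/read round-trips, including discontinuous spans", {
  corpus <- generate_corpus(default_config_nubeslike(), 60, seed = 11)
  has_disc <- any(vapply(corpus, function(s)
    any(vapply(s$scopes, function(sc) !sc$continuous, NA)), NA))
  expect_true(has_disc)
  dir <- withr::local_tempdir()
  write_standoff(corpus, dir)
  back <- load_corpus(dir, dialect = "generic")
  expect_length(back, length(corpus))
  for (i in seq_along(corpus)) {
    expect_identical(back[[i]]$text, corpus[[i]]$text)
    expect_identical(gold_fragment_keys(back[[i]]),
                     gold_fragment_keys(corpus[[i]]))
    expect_identical(sort(vapply(back[[i]]$cues, `[[`, "", "cue_class")),
                     sort(vapply(corpus[[i]]$cues, `[[`, "", "cue_class")))
  }
})

test_that("corpus statistics compute counts, percentages and coverage", {
  expect_error(corpus_statistics(list()), "empty")
  s1 <- annotated_sentence(
    "no dolor",
    cues = list(cue_annotation("T1", "negation", "syntactic",
                               data.frame(char_start = 0, char_end = 2),
                               "no")),
    scopes = list(scope_annotation("T2", "negation",
                                   data.frame(char_start = 3, char_end = 8),
                                   "T1")))
  s2 <- annotated_sentence("dolor leve")
  st <- corpus_statistics(list(s1, s2))
  expect_equal(st$pct_negated, 50.0)
  expect_equal(st$n_negation_cues, 1L)
  expect_equal(st$pct_continuous_scopes, 100.0)
  expect_equal(st$pct_scope_sentence_final[["negation"]], 100.0)
  expect_equal(top_k_cue_coverage(st, "negation", 1), 100.0)
  # no annotation lost or duplicated by segmentation / aggregation
  corpus <- generate_corpus(default_config_nubeslike(), 150, seed = 4)
  st2 <- corpus_statistics(corpus)
  expect_identical(st2$n_negation_cues + st2$n_uncertainty_cues,
                   sum(vapply(corpus, function(s) length(s$cues), 0L)))
  expect_equal(st2$pct_continuous_scopes + st2$pct_discontinuous_scopes,
               100)
  cls <- st2$pct_cues_by_class
  expect_equal(sum(cls[, "negation"]), 100, tolerance = 1e-9)
  expect_equal(sum(cls[, "uncertainty"]), 100, tolerance = 1e-9)
})

test_that("JSON-lines serialization round-trips a corpus", {
  corpus <- generate_corpus(default_config_nubeslike(), 25, seed = 9)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corpus, path)
  back <- read_corpus_jsonl(path)
  expect_length(back, length(corpus))
  for (i in seq_along(corpus)) {
    expect_identical(back[[i]]$text, corpus[[i]]$text)
    expect_identical(gold_fragment_keys(back[[i]]),
                     gold_fragment_keys(corpus[[i]]))
  }
})
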