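test_that("BIO conversion labels cues and scopes fragment by fragment", {
  alpha <- label_alphabet()
  expect_identical(to_bio(annotated_sentence("a b c d"), alpha),
                   rep("O", 4))
  expect_identical(to_bio(simple_neg_sentence(), alpha),
                   c("O", "O", "B-NEG", "B-NSCO", "I-NSCO", "I-NSCO"))
  # discontinuous scope: each fragment restarts its own B- run
  s <- annotated_sentence(
    "dolor con fiebre sin tos",
    cues = list(cue_annotation("T1", "negation", "syntactic",
                               data.frame(char_start = 17, char_end = 20),
                               "sin")),
    scopes = list(scope_annotation("T2", "negation",
                                   data.frame(char_start = c(0, 21),
                                              char_end = c(5, 24)), "T1")))
  expect_identical(to_bio(s, alpha),
                   c("B-NSCO", "O", "O", "B-NEG", "B-NSCO"))
})

test_that("label conflicts resolve cue over scope, negation over uncertainty", {
  # uncertainty scope spans tokens 2-4; a negation cue claims token 3
  s <- annotated_sentence(
    "posible masa sin derrame",
    cues = list(
      cue_annotation("T1", "uncertainty", "lexical",
                     data.frame(char_start = 0, char_end = 7), "posible"),
      cue_annotation("T2", "negation", "syntactic",
                     data.frame(char_start = 13, char_end = 16), "sin")),
    scopes = list(
      scope_annotation("T3", "uncertainty",
                       data.frame(char_start = 8, char_end = 24), "T1")))
  expect_identical(to_bio(s), c("B-UNC", "B-USCO", "B-NEG", "I-USCO"))
})

test_that("dictionaries cover tokens with reserved ids and restrict labels", {
  expect_error(build_dictionaries(list()), "empty")
  corpus <- list(annotated_sentence("no dolor"),
                 annotated_sentence("dolor"))
  d <- build_dictionaries(corpus)
  expect_identical(d$dt$size, 4L)  # 2 tokens + PAD + UNK
  expect_identical(d$dt$pad_id, 0L)
  expect_identical(d$dt$unk_id, 1L)
  # no uncertainty annotations -> negation-only alphabet
  expect_identical(d$alphabet$labels,
                   c("PAD", "O", "B-NEG", "I-NEG", "B-NSCO", "I-NSCO"))
  full <- label_alphabet()
  expect_identical(full$labels[1], "PAD")
  expect_identical(unname(full$to_id["PAD"]), 0L)
  expect_identical(id_to_label(full, label_to_id(full, full$labels)),
                   full$labels)
})

test_that("matrix encoding pads all five structures consistently", {
  corpus <- list(simple_neg_sentence())
  d <- build_dictionaries(corpus)
  b <- encode_matrices(corpus, d$dt, d$alphabet, j = 8)
  expect_identical(dim(b$T), c(1L, 8L))
  expect_identical(b$T[1, 7:8], c("PAD", "PAD"))
  expect_identical(b$L[1, 7:8], c("PAD", "PAD"))
  expect_identical(b$Tp[1, 7:8], c(0L, 0L))
  expect_identical(b$Lp[1, 7:8], c(0L, 0L))
  # every one-hot row sums to exactly 1, and argmax recovers Lp
  expect_true(all(apply(b$H, c(1, 2), sum) == 1))
  expect_identical(apply(b$H[1, , , drop = TRUE], 1, which.max) - 1L,
                   b$Lp[1, ])
  # refusing to truncate silently
  expect_error(encode_matrices(corpus, d$dt, d$alphabet, j = 3),
               "truncate")
  tb <- encode_matrices(corpus, d$dt, d$alphabet, j = 3, truncate = TRUE)
  expect_identical(tb$lengths, 3L)
  # unknown tokens at prediction time map to UNK
  b2 <- encode_matrices(list(annotated_sentence("zzz no")), d$dt,
                        d$alphabet)
  expect_identical(b2$Tp[1, 1], d$dt$unk_id)
})

test_that("entity decoding inverts BIO runs and repairs dangling I-", {
  expect_length(decode_entities(c("O", "O", "O")), 0)
  e <- decode_entities(c("O", "O", "B-NEG", "B-NSCO", "I-NSCO", "I-NSCO"))
  expect_length(e, 2)
  expect_identical(e[[1]]$token_indices, 3L)
  expect_identical(e[[2]]$token_indices, 4:6)
  expect_identical(e[[2]]$category, "NSCO")
  r <- decode_entities(c("I-NSCO", "I-NSCO"))
  expect_length(r, 1)
  expect_identical(r[[1]]$token_indices, 1:2)
  expect_error(decode_entities(c("O", "PAD")), "PAD")
})

test_that("BIO round trip reproduces every annotation fragment", {
  corpus <- generate_corpus(default_config_nubeslike(), 300, seed = 21)
  alpha <- label_alphabet()
  for (s in corpus) {
    labs <- to_bio(s, alpha)
    # label count conservation: one B- per annotation fragment
    n_frag <- sum(vapply(c(s$cues, s$scopes),
                         function(a) nrow(a$fragments), 0L))
    expect_identical(sum(startsWith(labs, "B-")), n_frag)
    expect_identical(entity_keys(decode_entities(labs)),
                     gold_fragment_keys(s))
  }
})

test_that("CoNLL TSV and dictionary JSON round-trip", {
  corpus <- generate_corpus(default_config_nubeslike(), 15, seed = 2)
  alpha <- label_alphabet()
  gold <- lapply(corpus, to_bio, alphabet = alpha)
  pred <- lapply(gold, function(g) replace(g, 1, "O"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_conll(corpus, gold, pred, path)
  back <- read_conll(path)
  expect_identical(back$gold, gold)
  expect_identical(back$pred, pred)
  expect_identical(back$tokens, lapply(corpus, function(s) s$tokens$text))
  d <- build_dictionaries(corpus)$dt
  jp <- withr::local_tempfile(fileext = ".json")
  write_token_dict(d, jp)
  d2 <- read_token_dict(jp)
  expect_identical(d2$to_id[d$tokens], d$to_id[d$tokens])
})
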