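test_that("token-level metrics reproduce the worked partial-match example", {
  # gold scope of three tokens, prediction covers only the first two:
  # precision 1, recall 2/3, F1 0.8
  gold <- list(c("B-NEG", "B-NSCO", "I-NSCO", "I-NSCO"))
  pred <- list(c("B-NEG", "B-NSCO", "I-NSCO", "O"))
  m <- token_prf(gold, pred, c("B-NSCO", "I-NSCO"))
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 0.8)
  expect_identical(m$support, 3L)
  # perfect prediction
  p <- token_prf(gold, gold)
  expect_equal(c(p$precision, p$recall, p$f1), c(1, 1, 1))
  # zero denominators are reported as 0 with defined = FALSE
  z <- token_prf(list(c("O", "O")), list(c("O", "O")), "B-NEG")
  expect_false(z$defined)
  expect_equal(z$f1, 0)
  expect_error(token_prf(list(c("O", "O")), list("O")), "mismatch")
})

test_that("token metrics equal an independent per-token tally", {
  set.seed(81)
  alpha <- label_alphabet()
  labs <- setdiff(alpha$labels, "PAD")
  gold <- replicate(20, sample(labs, sample(3:12, 1), replace = TRUE),
                    simplify = FALSE)
  pred <- lapply(gold, function(g)
    ifelse(runif(length(g)) < 0.3, sample(labs, length(g), TRUE), g))
  subset <- c("B-NEG", "I-NEG", "B-NSCO", "I-NSCO")
  m <- token_prf(gold, pred, subset)
  # brute-force recount, one token at a time
  correct <- predicted <- gn <- 0
  for (i in seq_along(gold)) for (t in seq_along(gold[[i]])) {
    gi <- gold[[i]][t] %in% subset
    pi <- pred[[i]][t] %in% subset
    gn <- gn + gi; predicted <- predicted + pi
    correct <- correct + (gi && pi && gold[[i]][t] == pred[[i]][t])
  }
  expect_equal(m$precision, correct / predicted)
  expect_equal(m$recall, correct / gn)
  expect_true(m$precision >= 0 && m$precision <= 1)
  expect_true(correct <= min(predicted, gn))
})

test_that("exact match requires identical token sets, matched 1:1", {
  g <- list(decode_entities(c("O", "O", "B-NSCO", "I-NSCO", "I-NSCO")))
  p_short <- list(decode_entities(c("O", "O", "B-NSCO", "I-NSCO", "O")))
  m <- exact_match_prf(g, p_short, "NSCO")
  expect_equal(m$precision, 0)
  expect_equal(m$recall, 0)
  ident <- exact_match_prf(g, g, "NSCO")
  expect_equal(ident$f1, 1)
  # duplicate identical predictions: only one counts
  p_dup <- list(c(g[[1]], g[[1]]))
  d <- exact_match_prf(g, p_dup, "NSCO")
  expect_equal(d$precision, 0.5)
  expect_equal(d$recall, 1)
})

test_that("support-weighted rollups reduce label rows to task scores", {
  rows <- published_label_rows()
  neg_cue <- weighted_rollup(rows, c("B-NEG", "I-NEG"))
  expect_equal(round(neg_cue$f1, 2), 0.93)
  expect_identical(neg_cue$support, 1423L + 120L)
  unc_scope <- weighted_rollup(rows, c("B-USCO", "I-USCO"))
  expect_equal(round(unc_scope$f1, 2), 0.79)
  # equal supports reduce to the arithmetic mean
  eq <- data.frame(label = c("A", "B"), precision = c(0.4, 0.8),
                   recall = c(0.5, 0.7), f1 = c(0.44, 0.75),
                   support = c(10L, 10L))
  m <- weighted_rollup(eq, c("A", "B"))
  expect_equal(m$f1, mean(eq$f1))
  expect_error(weighted_rollup(rows, c("B-NEG", "missing")), "missing")
})

test_that("the label report carries per-label metrics and both rollups", {
  corpus <- generate_corpus(default_config_nubeslike(), 60, seed = 91)
  alpha <- label_alphabet()
  gold <- lapply(corpus, to_bio, alphabet = alpha)
  # corrupt predictions by deleting random annotated tokens to O
  set.seed(92)
  pred <- lapply(gold, function(g)
    ifelse(g != "O" & runif(length(g)) < 0.25, "O", g))
  rep_ <- label_report(gold, pred, alpha)
  expect_setequal(rep_$per_label$label, setdiff(alpha$labels, "PAD"))
  expect_identical(
    rep_$rollups$NEG$partial$support,
    sum(rep_$per_label$support[rep_$per_label$label %in%
                                 c("B-NEG", "I-NEG")]))
  # deletions can only break exact matches: exact F1 <= partial F1
  for (cat_ in names(rep_$rollups)) {
    expect_lte(rep_$rollups[[cat_]]$exact$f1,
               rep_$rollups[[cat_]]$partial$f1 + 1e-12)
  }
})

test_that("inter-annotator agreement follows the reference-annotator design", {
  corpus <- generate_corpus(default_config_nubeslike(), 40, seed = 93)
  self <- iaa(corpus, corpus, level = "token")
  expect_true(all(self$f1[self$defined] == 1))
  self_e <- iaa(corpus, corpus, level = "entity")
  expect_true(all(self_e$f1[self_e$defined] == 1))
  # the two-annotator scope example: A annotates three tokens,
  # B two of them -> token F1 0.8, entity agreement 0
  mk <- function(end) annotated_sentence(
    "Sin dolor toraxico agudo",
    cues = list(cue_annotation("T1", "negation", "syntactic",
                               data.frame(char_start = 0, char_end = 3),
                               "Sin")),
    scopes = list(scope_annotation("T2", "negation",
                                   data.frame(char_start = 4,
                                              char_end = end), "T1")))
  a <- list(mk(24)); b <- list(mk(18))
  tok <- iaa(a, b, level = "token")
  row <- tok[tok$category == "Negation scope", ]
  expect_equal(row$f1, 0.8)
  ent <- iaa(a, b, level = "entity")
  expect_equal(ent[ent$category == "Negation scope", "f1"], 0)
  expect_equal(ent[ent$category == "Negation cue", "f1"], 1)
  expect_error(iaa(a, list(annotated_sentence("otra cosa"))),
               "same sentences")
})

test_that("cross-validation partitions, averages and reproduces by seed", {
  corpus <- generate_corpus(config_separable(), 30, seed = 95)
  alpha <- build_dictionaries(corpus)$alphabet
  factory <- function(train) make_rule_tagger(alpha)
  expect_error(cross_validate(corpus, k = 31, factory), "exceeds")
  cv <- cross_validate(corpus, k = 5, factory, seed = 7, alphabet = alpha)
  # folds are disjoint, near-equal, and their union is the corpus
  expect_identical(sort(unique(cv$assignments)), 1:5)
  expect_true(all(abs(table(cv$assignments) - 6) == 0))
  cv2 <- cross_validate(corpus, k = 5, factory, seed = 7, alphabet = alpha)
  expect_identical(cv$assignments, cv2$assignments)
  # the averaged report is the unweighted mean of the fold metrics
  per_fold <- vapply(cv$folds, function(r)
    r$rollups$NEG$partial$f1, 0)
  expect_equal(cv$average$rollups$NEG$partial$f1, mean(per_fold))
})
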