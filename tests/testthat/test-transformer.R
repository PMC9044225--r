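tiny_tokenizer <- function() {
  corpus <- list(annotated_sentence(
    "la la biopsia muestra muestra algo algo"))
  build_wordpiece_vocab(corpus, min_count = 2)
}

test_that("WordPiece splits rare words and reconstructs them from pieces", {
  tk <- tiny_tokenizer()
  # frequent words stay whole
  expect_identical(wordpiece_tokenize(tk, "la"), "la")
  expect_identical(wordpiece_tokenize(tk, "muestra"), "muestra")
  # rare words split into continuation-marked pieces
  pieces <- wordpiece_tokenize(tk, "biopsia")
  expect_gt(length(pieces), 1)
  expect_true(all(startsWith(pieces[-1], "##")))
  expect_identical(paste(gsub("^##", "", pieces), collapse = ""), "biopsia")
  # characters never seen map the word to [UNK]
  expect_identical(wordpiece_tokenize(tk, "жж"), "[UNK]")
})

test_that("sub-word alignment adds specials and covers every word", {
  tk <- tiny_tokenizer()
  al <- align_subwords(c("la", "muestra", "algo"), tk)
  expect_identical(al$subtokens[1], "[CLS]")
  expect_identical(al$subtokens[length(al$subtokens)], "[SEP]")
  # no-split case: identity shifted by one for [CLS]
  expect_identical(al$word_to_subtokens,
                   list(c(2L, 2L), c(3L, 3L), c(4L, 4L)))
  al2 <- align_subwords(c("la", "biopsia"), tk)
  rngs <- al2$word_to_subtokens
  expect_identical(rngs[[1]], c(2L, 2L))
  expect_gt(rngs[[2]][2], rngs[[2]][1])
  # ranges are disjoint, ordered, and cover all non-special positions
  covered <- unlist(lapply(rngs, function(r) r[1]:r[2]))
  expect_identical(covered,
                   setdiff(seq_along(al2$subtokens), al2$special_positions))
})

test_that("label expansion and post-processing are mutually inverse", {
  tk <- tiny_tokenizer()
  al <- align_subwords(c("la", "biopsia", "algo"), tk)
  labs <- c("O", "B-NSCO", "I-NSCO")
  ex <- expand_labels(labs, al)
  expect_identical(ex[1], "PAD")
  expect_identical(ex[length(ex)], "PAD")
  # continuations of a B-X word carry I-X
  rng <- al$word_to_subtokens[[2]]
  expect_identical(ex[rng[1]], "B-NSCO")
  if (rng[2] > rng[1])
    expect_true(all(ex[(rng[1] + 1):rng[2]] == "I-NSCO"))
  out <- postprocess(ex, al)
  expect_identical(as.vector(out), labs)
  expect_false(attr(out, "truncated"))
  expect_error(expand_labels(c("O", "O"), al), "word count")
  # round trip holds across generated sentences
  corpus <- generate_corpus(default_config_nubeslike(), 150, seed = 41)
  wp <- build_wordpiece_vocab(corpus)
  alpha <- label_alphabet()
  for (s in corpus) {
    a <- align_subwords(s$tokens$text, wp)
    g <- to_bio(s, alpha)
    expect_identical(as.vector(postprocess(expand_labels(g, a), a)), g)
  }
})

test_that("the softmax head is exact, stable and shift-invariant", {
  d <- 6; K <- 4
  head <- list(W = matrix(0, d, K), b = rep(0, K))
  P <- classify_head(matrix(rnorm(12), 2, d), head)
  expect_equal(P, matrix(1 / K, 2, K), tolerance = 1e-12)
  # hand-computed two-label case: logits (ln 3, 0) -> (0.75, 0.25)
  h2 <- list(W = diag(2), b = c(0, 0))
  expect_equal(as.numeric(classify_head(matrix(c(log(3), 0), 1, 2), h2)),
               c(0.75, 0.25), tolerance = 1e-12)
  # rows sum to one even at extreme magnitudes, and shifting all logits
  # of a row changes nothing
  R <- matrix(c(1000, 1001, 999, -1000, -999, -1001), 2, 3, byrow = TRUE)
  h3 <- list(W = diag(3), b = rep(0, 3))
  P3 <- classify_head(R, h3)
  expect_equal(rowSums(P3), c(1, 1), tolerance = 1e-9)
  expect_equal(classify_head(R + 7, h3), P3, tolerance = 1e-9)
  expect_error(classify_head(matrix(c(1, Inf), 1, 2), h3), "non-finite")
})

test_that("special positions are masked out of the loss entirely", {
  ns <- asNamespace("negscope")
  set.seed(51)
  logits <- ns$nsc_param(matrix(rnorm(15), 5, 3))
  tape <- ns$ad_tape()
  node <- ns$ad_leaf(tape, logits)
  loss <- ns$ad_mean_xent(tape, node, targets = c(1, 2, 3, 2, 1),
                          weights = c(0, 1, 1, 1, 0))
  ns$ad_backward(tape, loss)
  expect_true(all(logits$grad[c(1, 5), ] == 0))
  expect_true(any(logits$grad[2:4, ] != 0))
})

test_that("the full encoder graph backpropagates exact gradients", {
  ns <- asNamespace("negscope")
  set.seed(53)
  cfg <- finetune_config(max_sequence_length = 16, dim = 8, layers = 2,
                         heads = 2, ffn = 12, seed = 1)
  K <- 4
  tp <- ns$transformer_init_params(10, 16, cfg, K)
  tp$layers[[1]]$rb$value[] <- rnorm(length(tp$layers[[1]]$rb$value)) * 0.3
  ids <- c(1, 4, 7, 2, 9); targ <- c(1, 2, 3, 2, 1); wts <- c(0, 1, 1, 1, 0)
  runl <- function() {
    tape <- ns$ad_tape()
    lo <- ns$transformer_logits_node(tape, tp, ids, cfg, K)
    list(tape = tape, loss = ns$ad_mean_xent(tape, lo, targ, wts))
  }
  r <- runl()
  ns$ad_backward(r$tape, r$loss)
  for (pick in list("Etok", c("layers", "1", "Wq"), c("layers", "1", "rb"),
                    c("layers", "2", "W1"), c("layers", "1", "g1"), "Wh")) {
    p <- tp
    for (k in pick)
      p <- p[[if (grepl("^[0-9]+$", k)) as.integer(k) else k]]
    f <- function(v) {
      old <- p$value; p$value <- v; on.exit(p$value <- old)
      as.numeric(runl()$loss$value)
    }
    expect_lt(max(abs(p$grad - ns$numeric_grad(f, p$value))), 1e-6)
    p$grad[] <- 0
  }
  # the taped graph and the plain numeric forward agree exactly
  freeze <- function(x) if (inherits(x, "nsc_param")) x$value else
    if (is.list(x)) lapply(x, freeze) else x
  tape <- ns$ad_tape()
  lo <- ns$transformer_logits_node(tape, tp, ids, cfg, K)
  expect_equal(lo$value,
               ns$transformer_numeric_logits(freeze(tp), ids, cfg),
               tolerance = 1e-12)
})

test_that("fine-tuning is seed-deterministic and truncation preserves shape", {
  corpus <- generate_corpus(config_separable(), 16, seed = 61)
  alpha <- build_dictionaries(corpus)$alphabet
  cfg <- finetune_config(max_sequence_length = 32, batch = 8, epochs = 2,
                         learning_rate = 1e-3, seed = 5, dim = 8,
                         layers = 1, heads = 2, ffn = 16)
  m1 <- finetune(corpus, cfg, alphabet = alpha)
  m2 <- finetune(corpus, cfg, alphabet = alpha)
  expect_identical(m1$loss_trace, m2$loss_trace)
  # a sentence longer than the maximum length still yields one label per
  # word, with the truncated tail labeled O and flagged
  long_toks <- rep(c("control", "masa"), 40)
  p <- predict(m1, list(long_toks))[[1]]
  expect_length(p, 80)
  expect_true(attr(p, "truncated"))
  expect_true(all(p[60:80] == "O"))
  # empty input contract
  expect_identical(length(predict(m1, list())), 0L)
})
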