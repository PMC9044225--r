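# Transformer-encoder tagger: WordPiece sub-word tokenization with label
# alignment, a self-attention encoder producing one contextual vector per
# sub-token, a softmax classification head, and special-token
# post-processing back to word-level BIO labels.

#' Fine-tuning configuration for the transformer tagger
#'
#' Published defaults: maximum sequence length 256 sub-tokens, batch size
#' 64, five epochs. The tiny random-initialized encoder used for
#' desk-scale work defaults to 2 layers, model dimension 32, 2 attention
#' heads, feed-forward width 128.
#'
#' @param max_sequence_length Maximum sub-tokens incl. `[CLS]`/`[SEP]`
#'   (>= 3); longer inputs are truncated and the affected words reported.
#' @param batch Minibatch size in sentences.
#' @param epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param seed RNG seed (initialization, shuffling).
#' @param dim,layers,heads,ffn Tiny-encoder dimensions (`dim` divisible by
#'   `heads`).
#' @param clip Global gradient-norm clip.
#' @export
finetune_config <- function(max_sequence_length = 256L, batch = 64L,
                            epochs = 5L, learning_rate = 1e-3, seed = 13L,
                            dim = 32L, layers = 2L, heads = 2L, ffn = 128L,
                            clip = 5) {
  stopifnot(max_sequence_length >= 3L, batch >= 1L, epochs >= 1L,
            learning_rate > 0, dim %% heads == 0L)
  structure(list(max_sequence_length = as.integer(max_sequence_length),
                 batch = as.integer(batch), epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 dim = as.integer(dim), layers = as.integer(layers),
                 heads = as.integer(heads), ffn = as.integer(ffn),
                 clip = clip),
            class = "nsc_finetune_config")
}

# --- WordPiece tokenizer ----------------------------------------------------

#' Build a WordPiece vocabulary from a corpus
#'
#' Frequent (lowercased) words become whole-word units; everything else is
#' split greedily into the longest known pieces, continuations prefixed
#' with `"##"`. All single characters of the corpus are included so every
#' word can be segmented; a character never seen maps the word to
#' `[UNK]`.
#'
#' @param corpus List of annotated sentences.
#' @param min_count Minimum frequency for a whole-word unit.
#' @return An `nsc_wordpiece` tokenizer.
#' @export
build_wordpiece_vocab <- function(corpus, min_count = 2L) {
  words <- tolower(unlist(lapply(corpus, function(s) s$tokens$text),
                          use.names = FALSE))
  freq <- table(words)
  whole <- names(freq)[freq >= min_count]
  chars <- unique(unlist(strsplit(names(freq), ""), use.names = FALSE))
  vocab <- unique(c("[PAD]", "[UNK]", "[CLS]", "[SEP]",
                    whole, chars, paste0("##", chars)))
  structure(list(vocab = vocab,
                 to_id = stats::setNames(seq_along(vocab) - 1L, vocab)),
            class = "nsc_wordpiece")
}

#' Segment one word into WordPiece sub-tokens
#'
#' Greedy longest-match-first segmentation; continuation pieces carry the
#' `"##"` prefix. Returns `"[UNK]"` when the word cannot be segmented.
#'
#' @param tokenizer An `nsc_wordpiece`.
#' @param word A single word.
#' @return Character vector of at least one sub-token.
#' @export
wordpiece_tokenize <- function(tokenizer, word) {
  w <- tolower(word)
  if (!nzchar(w)) return("[UNK]")
  pieces <- character(0)
  pos <- 1L
  n <- nchar(w)
  while (pos <= n) {
    len <- n - pos + 1L
    found <- NULL
    while (len >= 1L) {
      cand <- substr(w, pos, pos + len - 1L)
      key <- if (pos > 1L) paste0("##", cand) else cand
      if (key %in% tokenizer$vocab) { found <- key; break }
      len <- len - 1L
    }
    if (is.null(found)) return("[UNK]")
    pieces <- c(pieces, found)
    pos <- pos + len
  }
  pieces
}

#' Align words to sub-token positions
#'
#' Tokenizes each word into sub-words, prepends `[CLS]`, appends `[SEP]`,
#' and records, per word, the contiguous range of sub-token positions it
#' occupies. Stripping `"##"` and concatenating a word's sub-tokens
#' reproduces the (lowercased) word.
#'
#' @param tokens Character vector of words, or a token table.
#' @param tokenizer An `nsc_wordpiece`.
#' @return An `nsc_alignment`: `subtokens`, `word_to_subtokens` (list of
#'   `c(first, last)` 1-based positions) and `special_positions`.
#' @export
align_subwords <- function(tokens, tokenizer) {
  words <- if (is.data.frame(tokens)) tokens$text else tokens
  sub <- "[CLS]"
  ranges <- vector("list", length(words))
  for (i in seq_along(words)) {
    pieces <- wordpiece_tokenize(tokenizer, words[i])
    ranges[[i]] <- c(length(sub) + 1L, length(sub) + length(pieces))
    sub <- c(sub, pieces)
  }
  sub <- c(sub, "[SEP]")
  structure(list(subtokens = sub, word_to_subtokens = ranges,
                 special_positions = c(1L, length(sub))),
            class = "nsc_alignment")
}

#' Expand word-level BIO labels to sub-token positions
#'
#' The first sub-token of a word keeps the word's label; continuation
#' sub-tokens of a `B-X` word receive `I-X`; continuations of `I-X` / `O`
#' repeat the word label; special positions receive `PAD`.
#'
#' @param labels Word-level BIO labels.
#' @param align An `nsc_alignment` for the same words.
#' @return Character vector over all sub-token positions.
#' @export
expand_labels <- function(labels, align) {
  if (length(labels) != length(align$word_to_subtokens))
    stop("label count ", length(labels), " != word count ",
         length(align$word_to_subtokens))
  out <- rep("PAD", length(align$subtokens))
  for (i in seq_along(labels)) {
    rng <- align$word_to_subtokens[[i]]
    lab <- labels[i]
    out[rng[1L]] <- lab
    if (rng[2L] > rng[1L]) {
      cont <- if (startsWith(lab, "B-"))
        paste0("I-", substr(lab, 3L, nchar(lab))) else lab
      out[(rng[1L] + 1L):rng[2L]] <- cont
    }
  }
  out
}

#' Reduce sub-token labels back to word level
#'
#' Drops special positions; each word takes its first sub-token's label.
#' Words beyond `n_words` coverage (truncated away) are labeled `O` and
#' flagged in the `"truncated"` attribute.
#'
#' @param subtoken_labels Labels over all sub-token positions of `align`.
#' @param align The `nsc_alignment` used to produce them.
#' @param max_positions Optional cap: ranges beyond it count as truncated.
#' @return Word-level label vector (length = word count) with attribute
#'   `truncated` (logical).
#' @export
postprocess <- function(subtoken_labels, align, max_positions = NULL) {
  nw <- length(align$word_to_subtokens)
  out <- character(nw)
  truncated <- FALSE
  for (i in seq_len(nw)) {
    first <- align$word_to_subtokens[[i]][1L]
    if (!is.null(max_positions) && first > max_positions - 1L) {
      out[i] <- "O"; truncated <- TRUE
    } else if (first > length(subtoken_labels)) {
      out[i] <- "O"; truncated <- TRUE
    } else {
      out[i] <- subtoken_labels[first]
    }
  }
  attr(out, "truncated") <- truncated
  out
}

#' Softmax classification head over contextual vectors
#'
#' Row `t` of the result is `softmax(W_o R_t + b_o)`, computed with
#' max-subtraction for numerical stability; every row sums to 1.
#'
#' @param R `n x d` matrix of contextual vectors.
#' @param head List with `W` (`d x K`) and `b` (length `K`).
#' @return `n x K` probability matrix.
#' @export
classify_head <- function(R, head) {
  R <- as.matrix(R)
  if (!all(is.finite(R))) stop("non-finite contextual vectors")
  logits <- sweep(R %*% head$W, 2L, as.numeric(head$b), `+`)
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# --- tiny encoder -----------------------------------------------------------

# fixed sinusoidal position encodings: generalize across sequence lengths
# a tiny training corpus cannot cover, unlike learned absolute positions
sinusoidal_positions <- function(maxlen, d) {
  pos <- seq_len(maxlen) - 1L
  i <- seq_len(d)
  angle <- outer(pos, 1 / 10000^((2 * ((i - 1L) %/% 2L)) / d))
  out <- matrix(0, maxlen, d)
  odd <- seq(1L, d, by = 2L)
  out[, odd] <- sin(angle[, odd, drop = FALSE])
  if (d > 1L) {
    even <- seq(2L, d, by = 2L)
    out[, even] <- cos(angle[, even, drop = FALSE])
  }
  out
}

# symmetric log-bucketed relative distances (T5-style), so attention can
# condition on "how far and on which side" and extrapolate across lengths
rel_buckets <- function(n, n_exact = 8L, n_log = 4L, max_dist = 64L) {
  d <- outer(seq_len(n), seq_len(n), `-`)  # i - j
  mag <- pmin(abs(d), max_dist)
  b <- ifelse(mag <= n_exact, mag,
              n_exact + pmin(n_log - 1L, floor(
                log(pmax(mag, n_exact + 1L) / n_exact) /
                  log(max_dist / n_exact) * n_log)))
  n_side <- n_exact + n_log + 1L
  matrix(as.integer(ifelse(d >= 0, b + 1L, b + n_side + 1L)), n, n)
}

n_rel_buckets <- function() 2L * (8L + 4L + 1L)

transformer_init_params <- function(vocab, maxlen, cfg, K) {
  d <- cfg$dim
  gl <- function(nr, nc, s = sqrt(1 / nr))
    matrix(stats::rnorm(nr * nc, 0, s), nr, nc)
  layer <- function() list(
    Wq = nsc_param(gl(d, d)), Wk = nsc_param(gl(d, d)),
    Wv = nsc_param(gl(d, d)), Wo = nsc_param(gl(d, d)),
    rb = nsc_param(matrix(0, cfg$heads, n_rel_buckets())),
    bo = nsc_param(matrix(0, 1L, d)),
    g1 = nsc_param(matrix(1, 1L, d)), c1 = nsc_param(matrix(0, 1L, d)),
    W1 = nsc_param(gl(d, cfg$ffn)), b1 = nsc_param(matrix(0, 1L, cfg$ffn)),
    W2 = nsc_param(gl(cfg$ffn, d)), b2 = nsc_param(matrix(0, 1L, d)),
    g2 = nsc_param(matrix(1, 1L, d)), c2 = nsc_param(matrix(0, 1L, d)))
  list(Etok = nsc_param(gl(vocab, d, 0.1)),
       Epos = sinusoidal_positions(maxlen, d) * 0.5,
       g0 = nsc_param(matrix(1, 1L, d)), c0 = nsc_param(matrix(0, 1L, d)),
       layers = lapply(seq_len(cfg$layers), function(i) layer()),
       Wh = nsc_param(gl(d, K)), bh = nsc_param(matrix(0, 1L, K)))
}

flatten_params <- function(params) {
  out <- list()
  walk <- function(x) {
    if (inherits(x, "nsc_param")) out[[length(out) + 1L]] <<- x
    else if (is.list(x)) for (e in x) walk(e)
  }
  walk(params)
  out
}

# encoder graph on the tape: sub-token ids (1-based rows) -> logits node
transformer_logits_node <- function(tape, params, ids, cfg, K) {
  n <- length(ids)
  d <- cfg$dim
  dk <- d %/% cfg$heads
  X <- ad_cadd(tape, ad_rows(tape, ad_leaf(tape, params$Etok), ids),
               params$Epos[seq_len(n), , drop = FALSE])
  X <- ad_layernorm(tape, X, ad_leaf(tape, params$g0),
                    ad_leaf(tape, params$c0))
  bmat <- rel_buckets(n)
  # entropy-invariant scaling: sharpen attention logits with log sequence
  # length so attention does not dilute on sentences longer than trained
  lscale <- log(n + 1) / log(16)
  for (ly in params$layers) {
    Q <- ad_matmul(tape, X, ad_leaf(tape, ly$Wq))
    Kx <- ad_matmul(tape, X, ad_leaf(tape, ly$Wk))
    V <- ad_matmul(tape, X, ad_leaf(tape, ly$Wv))
    rb <- ad_leaf(tape, ly$rb)
    head_out <- vector("list", cfg$heads)
    for (hh in seq_len(cfg$heads)) {
      rng <- ((hh - 1L) * dk + 1L):(hh * dk)
      S <- ad_cmul(tape, ad_matmul_tB(tape, ad_cols(tape, Q, rng),
                                      ad_cols(tape, Kx, rng)),
                   lscale / sqrt(dk))
      S <- ad_add_gather(tape, S, ad_rows(tape, rb, hh), bmat)
      A <- ad_softmax_rows(tape, S)
      head_out[[hh]] <- ad_matmul(tape, A, ad_cols(tape, V, rng))
    }
    O <- head_out[[1L]]
    if (cfg$heads > 1L) for (hh in 2L:cfg$heads)
      O <- ad_hconcat(tape, O, head_out[[hh]])
    O <- ad_add(tape, ad_matmul(tape, O, ad_leaf(tape, ly$Wo)),
                ad_leaf(tape, ly$bo))
    X <- ad_layernorm(tape, ad_add(tape, X, O), ad_leaf(tape, ly$g1),
                      ad_leaf(tape, ly$c1))
    FF <- ad_add(tape, ad_matmul(
      tape, ad_relu(tape, ad_add(tape, ad_matmul(tape, X,
                                                 ad_leaf(tape, ly$W1)),
                                 ad_leaf(tape, ly$b1))),
      ad_leaf(tape, ly$W2)), ad_leaf(tape, ly$b2))
    X <- ad_layernorm(tape, ad_add(tape, X, FF), ad_leaf(tape, ly$g2),
                      ad_leaf(tape, ly$c2))
  }
  ad_add(tape, ad_matmul(tape, X, ad_leaf(tape, params$Wh)),
         ad_leaf(tape, params$bh))
}

#' Fine-tune the transformer tagger
#'
#' Trains a compact randomly initialized self-attention encoder (token +
#' position embeddings, residual multi-head attention and feed-forward
#' blocks with layer normalization) with a softmax token-classification
#' head, minimizing cross-entropy over non-special sub-token positions.
#' Continuation sub-tokens are supervised with `I-X`; special positions
#' (`[CLS]`, `[SEP]`) are masked out of the loss. Deterministic given
#' `cfg$seed`.
#'
#' @param corpus Training corpus of annotated sentences.
#' @param cfg A [finetune_config()].
#' @param alphabet Label alphabet (defaults to the corpus's).
#' @param tokenizer Optional pre-built [build_wordpiece_vocab()] tokenizer.
#' @return An object of class `nsc_transformer` with fitted weights and a
#'   per-epoch mean loss trace.
#' @export
finetune <- function(corpus, cfg = finetune_config(), alphabet = NULL,
                     tokenizer = NULL) {
  alphabet <- alphabet %||% build_dictionaries(corpus)$alphabet
  tokenizer <- tokenizer %||% build_wordpiece_vocab(corpus)
  K <- alphabet$size
  maxlen <- cfg$max_sequence_length
  prep <- lapply(corpus, function(s) {
    align <- align_subwords(s$tokens$text, tokenizer)
    labs <- expand_labels(to_bio(s, alphabet), align)
    ids <- unname(tokenizer$to_id[align$subtokens]) + 1L
    keep <- seq_len(min(length(ids), maxlen))
    w <- as.numeric(!(align$subtokens %in% c("[CLS]", "[SEP]", "[PAD]")))
    list(ids = ids[keep],
         targets = label_to_id(alphabet, labs)[keep] + 1L,
         weights = w[keep])
  })
  prep <- Filter(function(p) sum(p$weights) > 0, prep)
  with_local_seed(cfg$seed, {
    params <- transformer_init_params(length(tokenizer$vocab), maxlen, cfg, K)
    flat <- flatten_params(params)
    trace <- numeric(0)
    step <- 0L
    steps_per_epoch <- ceiling(length(prep) / cfg$batch)
    total_steps <- cfg$epochs * steps_per_epoch
    warmup <- max(1L, round(0.1 * total_steps))
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(length(prep))
      losses <- numeric(0)
      for (chunk in split(ord, ceiling(seq_along(ord) / cfg$batch))) {
        zero_grads(flat)
        for (s in chunk) {
          p <- prep[[s]]
          tape <- ad_tape()
          logits <- transformer_logits_node(tape, params, p$ids, cfg, K)
          loss <- ad_mean_xent(tape, logits, p$targets, p$weights)
          lv <- as.numeric(loss$value)
          if (!is.finite(lv))
            stop("fine-tuning diverged (non-finite loss) at epoch ", epoch)
          losses <- c(losses, lv)
          ad_backward(tape, loss, init = 1 / length(chunk))
        }
        step <- step + 1L
        # linear warmup then linear decay, the standard fine-tuning schedule
        lr <- cfg$learning_rate * if (step <= warmup) step / warmup else
          max(0.02, (total_steps - step) / (total_steps - warmup))
        adam_step(flat, lr, step, clip = cfg$clip)
      }
      trace <- c(trace, mean(losses))
      nsc_log(sprintf("transformer epoch %d/%d  loss %.4f", epoch,
                      cfg$epochs, mean(losses)), level = "debug")
    }
    freeze <- function(x) {
      if (inherits(x, "nsc_param")) x$value
      else if (is.list(x)) lapply(x, freeze)
      else x
    }
    structure(list(weights = freeze(params), tokenizer = tokenizer,
                   alphabet = alphabet, cfg = cfg, loss_trace = trace),
              class = "nsc_transformer")
  })
}

# numeric forward (no tape); returns n x K logits for sub-token ids
transformer_numeric_logits <- function(w, ids, cfg) {
  n <- length(ids)
  d <- cfg$dim; dk <- d %/% cfg$heads
  ln <- function(x, g, c) {
    mu <- rowMeans(x); xc <- x - mu
    sd_ <- sqrt(rowMeans(xc * xc) + 1e-5)
    sweep(sweep(xc / sd_, 2L, as.numeric(g), `*`), 2L, as.numeric(c), `+`)
  }
  X <- w$Etok[ids, , drop = FALSE] + w$Epos[seq_len(n), , drop = FALSE]
  X <- ln(X, w$g0, w$c0)
  bmat <- rel_buckets(n)
  lscale <- log(n + 1) / log(16)
  for (ly in w$layers) {
    Q <- X %*% ly$Wq; Kx <- X %*% ly$Wk; V <- X %*% ly$Wv
    O <- NULL
    for (hh in seq_len(cfg$heads)) {
      rng <- ((hh - 1L) * dk + 1L):(hh * dk)
      S <- tcrossprod(Q[, rng, drop = FALSE], Kx[, rng, drop = FALSE]) *
        (lscale / sqrt(dk)) + matrix(ly$rb[hh, bmat], n, n)
      z <- S - apply(S, 1L, max); A <- exp(z) / rowSums(exp(z))
      Oh <- A %*% V[, rng, drop = FALSE]
      O <- if (is.null(O)) Oh else cbind(O, Oh)
    }
    X <- ln(X + sweep(O %*% ly$Wo, 2L, as.numeric(ly$bo), `+`),
            ly$g1, ly$c1)
    FF <- sweep(pmax(sweep(X %*% ly$W1, 2L, as.numeric(ly$b1), `+`), 0) %*%
                  ly$W2, 2L, as.numeric(ly$b2), `+`)
    X <- ln(X + FF, ly$g2, ly$c2)
  }
  sweep(X %*% w$Wh, 2L, as.numeric(w$bh), `+`)
}

#' Predict word-level BIO labels with a fine-tuned transformer
#'
#' Sub-tokenizes each sentence, encodes it, takes the argmax label per
#' sub-token (PAD excluded at non-special positions), and reduces to word
#' level via each word's first sub-token. Output length always equals the
#' input word count, including truncated inputs (truncated tails are `O`).
#'
#' @param object A trained `nsc_transformer`.
#' @param sentences List of annotated sentences or character vectors of
#'   tokens.
#' @param ... Unused.
#' @return List of word-level label vectors (each carrying a `truncated`
#'   attribute).
#' @export
predict.nsc_transformer <- function(object, sentences, ...) {
  cfg <- object$cfg
  lapply(sentences, function(s) {
    toks <- if (is.character(s)) s else s$tokens$text
    if (length(toks) == 0L) {
      out <- character(0); attr(out, "truncated") <- FALSE
      return(out)
    }
    align <- align_subwords(toks, object$tokenizer)
    ids <- unname(object$tokenizer$to_id[align$subtokens]) + 1L
    keep <- seq_len(min(length(ids), cfg$max_sequence_length))
    logits <- transformer_numeric_logits(object$weights, ids[keep], cfg)
    logits[, 1L] <- -Inf  # PAD column
    labs <- id_to_label(object$alphabet,
                        apply(logits, 1L, which.max) - 1L)
    postprocess(labs, align, max_positions = cfg$max_sequence_length)
  })
}

#' @export
print.nsc_transformer <- function(x, ...) {
  cat(sprintf(
    "<nsc_transformer> %d layers, dim %d, %d heads, |vocab| %d, %d epochs (final loss %.4f)\n",
    x$cfg$layers, x$cfg$dim, x$cfg$heads, length(x$tokenizer$vocab),
    length(x$loss_trace), utils::tail(x$loss_trace, 1L)))
  invisible(x)
}
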