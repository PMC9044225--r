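# Recurrent tagger: pretrained-embedding lookup, bidirectional LSTM
# encoding (forward and backward passes computed independently, states
# concatenated per token), and a linear-chain CRF output layer trained by
# exact negative log-likelihood.

#' Training configuration for the BiLSTM-CRF tagger
#'
#' Defaults are the published hyperparameters of the approach: learning
#' rate 0.001, dropout 0.5, 60 epochs, hidden size 300, batch size 512.
#' Adam is the optimizer; gradients are clipped at global norm 5.
#'
#' @param learning_rate Adam step size.
#' @param dropout Dropout probability on the encoder output, in `[0, 1)`.
#' @param epochs Training epochs.
#' @param hidden LSTM hidden size per direction.
#' @param batch Minibatch size in sentences.
#' @param seed RNG seed governing initialization, shuffling and dropout.
#' @param patience Optional early-stop patience (epochs without train-loss
#'   improvement).
#' @param clip Global gradient-norm clip.
#' @param trainable_embeddings Update embedding rows during training.
#' @export
train_config <- function(learning_rate = 0.001, dropout = 0.5, epochs = 60L,
                         hidden = 300L, batch = 512L, seed = 13L,
                         patience = NULL, clip = 5,
                         trainable_embeddings = TRUE) {
  stopifnot(learning_rate > 0, dropout >= 0, dropout < 1, epochs >= 1,
            hidden >= 1, batch >= 1)
  structure(list(learning_rate = learning_rate, dropout = dropout,
                 epochs = as.integer(epochs), hidden = as.integer(hidden),
                 batch = as.integer(batch), seed = as.integer(seed),
                 patience = patience, clip = clip,
                 trainable_embeddings = trainable_embeddings),
            class = "nsc_train_config")
}

#' Load pre-trained word vectors for a token dictionary
#'
#' Reads word2vec/fastText text format (header line `"count dim"`, then
#' one `"token v1 ... vd"` line each). In-vocabulary rows are copied;
#' out-of-vocabulary rows are drawn from a seeded normal(0, 0.1); the PAD
#' row is all-zero. With `source = "random"` (or `path = NULL`) the whole
#' matrix is random-initialized, the documented fallback when no vector
#' file is available.
#'
#' @param path Vector file, or `NULL`.
#' @param dt Token dictionary from [build_dictionaries()].
#' @param seed RNG seed for out-of-vocabulary rows.
#' @param dim Vector dimension when `source = "random"` (default 300).
#' @param source `"file"` or `"random"`.
#' @return An `nsc_embedding`: list with `vectors`
#'   (`dt$size x d`), `dim`, `source` and `coverage` (fraction of
#'   non-reserved tokens found in the file).
#' @export
load_word_vectors <- function(path = NULL, dt, seed = 13L, dim = 300L,
                              source = c("file", "random")) {
  source <- match.arg(source)
  if (is.null(path)) source <- "random"
  with_local_seed(seed, {
    if (source == "random") {
      vec <- matrix(stats::rnorm(dt$size * dim, 0, 0.1), dt$size, dim)
      vec[dt$pad_id + 1L, ] <- 0
      structure(list(vectors = vec, dim = as.integer(dim),
                     source = "random", coverage = 0),
                class = "nsc_embedding")
    } else {
      lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
      header <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
      d <- as.integer(header[2L])
      if (is.na(d)) stop("malformed vector-file header: ", dQuote(lines[1L]))
      vec <- matrix(stats::rnorm(dt$size * d, 0, 0.1), dt$size, d)
      vec[dt$pad_id + 1L, ] <- 0
      covered <- 0L
      for (ln in lines[-1L]) {
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        if (length(parts) != d + 1L)
          stop("dimension mismatch in vector file at token ",
               dQuote(parts[1L]), ": expected ", d, " values")
        id <- dt$to_id[parts[1L]]
        if (!is.na(id)) {
          vec[id + 1L, ] <- as.numeric(parts[-1L])
          covered <- covered + 1L
        }
      }
      structure(list(vectors = vec, dim = d, source = "file",
                     coverage = covered / (dt$size - 2L)),
                class = "nsc_embedding")
    }
  })
}

#' Write an embedding matrix in word2vec text format
#' @param emb An `nsc_embedding`.
#' @param dt The token dictionary it indexes.
#' @param path Output file.
#' @export
write_word_vectors <- function(emb, dt, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(dt$tokens), emb$dim), con)
  for (tok in dt$tokens) {
    row <- emb$vectors[dt$to_id[[tok]] + 1L, ]
    writeLines(paste(tok, paste(formatC(row, format = "g", digits = 8),
                                collapse = " ")), con)
  }
  invisible(path)
}

bilstm_init_params <- function(vocab_rows, d, h, K, emb_values) {
  gl <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(1 / nr)), nr, nc)
  lstm_bias <- function() {
    b <- matrix(0, 1L, 4L * h)
    b[1L, (h + 1L):(2L * h)] <- 1  # forget-gate bias at 1
    b
  }
  list(E = nsc_param(emb_values),
       Wf = nsc_param(gl(d, 4L * h)), Uf = nsc_param(gl(h, 4L * h)),
       bf = nsc_param(lstm_bias()),
       Wb = nsc_param(gl(d, 4L * h)), Ub = nsc_param(gl(h, 4L * h)),
       bb = nsc_param(lstm_bias()),
       Wo = nsc_param(gl(2L * h, K)), bo = nsc_param(matrix(0, 1L, K)),
       trans = nsc_param(matrix(0, K, K)),
       start = nsc_param(matrix(0, 1L, K)),
       end = nsc_param(matrix(0, 1L, K)))
}

# one LSTM direction on the tape; xs is an n x d node; returns list of
# 1 x h hidden-state nodes in input order
ad_lstm_dir <- function(tape, xs, n, W, U, b, h, reverse = FALSE) {
  hs <- vector("list", n)
  hprev <- ad_const(tape, matrix(0, 1L, h))
  cprev <- ad_const(tape, matrix(0, 1L, h))
  order_ <- if (reverse) seq.int(n, 1L) else seq_len(n)
  for (t in order_) {
    xt <- ad_rows(tape, xs, t)
    z <- ad_add(tape, ad_add(tape, ad_matmul(tape, xt, W),
                             ad_matmul(tape, hprev, U)), b)
    ig <- ad_sigmoid(tape, ad_cols(tape, z, 1:h))
    fg <- ad_sigmoid(tape, ad_cols(tape, z, (h + 1L):(2L * h)))
    og <- ad_sigmoid(tape, ad_cols(tape, z, (2L * h + 1L):(3L * h)))
    gg <- ad_tanh(tape, ad_cols(tape, z, (3L * h + 1L):(4L * h)))
    cprev <- ad_add(tape, ad_mul(tape, fg, cprev), ad_mul(tape, ig, gg))
    hprev <- ad_mul(tape, og, ad_tanh(tape, cprev))
    hs[[t]] <- hprev
  }
  hs
}

# full sentence graph; returns the emissions node (n x K, PAD column masked)
bilstm_emissions_node <- function(tape, params, ids, h, K, pad_col,
                                  dropmask = NULL, emb_leaf = NULL) {
  E <- emb_leaf %||% ad_leaf(tape, params$E)
  xs <- ad_rows(tape, E, ids)
  n <- length(ids)
  hf <- ad_lstm_dir(tape, xs, n, ad_leaf(tape, params$Wf),
                    ad_leaf(tape, params$Uf), ad_leaf(tape, params$bf), h)
  hb <- ad_lstm_dir(tape, xs, n, ad_leaf(tape, params$Wb),
                    ad_leaf(tape, params$Ub), ad_leaf(tape, params$bb), h,
                    reverse = TRUE)
  rows <- lapply(seq_len(n), function(t) ad_hconcat(tape, hf[[t]], hb[[t]]))
  H <- ad_vconcat(tape, rows)
  if (!is.null(dropmask)) H <- ad_cmul(tape, H, dropmask)
  emis <- ad_add(tape, ad_matmul(tape, H, ad_leaf(tape, params$Wo)),
                 ad_leaf(tape, params$bo))
  mask <- matrix(0, n, K); mask[, pad_col] <- -1e6
  ad_cadd(tape, emis, mask)
}

#' Train the BiLSTM-CRF tagger
#'
#' Minimizes the mean CRF negative log-likelihood over the batch's
#' unpadded sentences by Adam, with dropout on the encoder output and
#' gradient clipping. PAD positions never enter the loss and the PAD label
#' column is masked out of the emission scores. Training is a
#' deterministic function of `cfg$seed`.
#'
#' @param batch An [encode_matrices()] bundle.
#' @param emb An `nsc_embedding` consistent with the batch's dictionary.
#' @param cfg A [train_config()].
#' @param dt The token dictionary (stored in the model for prediction).
#' @return An object of class `nsc_bilstm_crf` with the fitted parameters
#'   and the per-epoch mean loss trace.
#' @export
train_bilstm_crf <- function(batch, emb, cfg = train_config(), dt = NULL) {
  stopifnot(inherits(batch, "nsc_encoded_batch"),
            inherits(emb, "nsc_embedding"))
  alphabet <- batch$alphabet
  K <- alphabet$size
  pad_col <- 1L  # PAD id 0 -> column 1
  h <- cfg$hidden; d <- emb$dim
  keep <- which(batch$lengths > 0L)
  seqs <- lapply(keep, function(s) {
    n <- batch$lengths[s]
    list(ids = batch$Tp[s, seq_len(n)] + 1L,     # row index = id + 1
         gold = batch$Lp[s, seq_len(n)] + 1L)
  })
  with_local_seed(cfg$seed, {
    params <- bilstm_init_params(nrow(emb$vectors), d, h, K, emb$vectors)
    trainables <- if (cfg$trainable_embeddings) params else
      params[setdiff(names(params), "E")]
    trace <- numeric(0)
    step <- 0L
    best <- Inf; stale <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(length(seqs))
      losses <- numeric(0)
      for (chunk in split(ord, ceiling(seq_along(ord) / cfg$batch))) {
        zero_grads(trainables)
        bsz <- length(chunk)
        for (s in chunk) {
          sq <- seqs[[s]]
          n <- length(sq$ids)
          dropmask <- if (cfg$dropout > 0)
            matrix(stats::rbinom(n * 2L * h, 1L, 1 - cfg$dropout) /
                     (1 - cfg$dropout), n, 2L * h) else NULL
          tape <- ad_tape()
          emis <- bilstm_emissions_node(tape, params, sq$ids, h, K, pad_col,
                                        dropmask)
          loss <- ad_crf_nll(tape, emis, ad_leaf(tape, params$trans),
                             ad_leaf(tape, params$start),
                             ad_leaf(tape, params$end), sq$gold)
          lv <- as.numeric(loss$value)
          if (!is.finite(lv))
            stop("training diverged (non-finite loss) at epoch ", epoch)
          losses <- c(losses, lv)
          ad_backward(tape, loss, init = 1 / bsz)
        }
        step <- step + 1L
        adam_step(trainables, cfg$learning_rate, step, clip = cfg$clip)
      }
      trace <- c(trace, mean(losses))
      nsc_log(sprintf("bilstm-crf epoch %d/%d  loss %.4f", epoch,
                      cfg$epochs, mean(losses)), level = "debug")
      if (!is.null(cfg$patience)) {
        if (mean(losses) < best - 1e-6) { best <- mean(losses); stale <- 0L }
        else stale <- stale + 1L
        if (stale >= cfg$patience) break
      }
    }
    structure(list(weights = lapply(params, function(p) p$value),
                   dt = dt, alphabet = alphabet, cfg = cfg,
                   emb_source = emb$source, dim = d, loss_trace = trace),
              class = "nsc_bilstm_crf")
  })
}

# plain numeric forward pass (no tape) for prediction
bilstm_numeric_emissions <- function(w, ids, h, K) {
  n <- length(ids)
  xs <- w$E[ids, , drop = FALSE]
  run <- function(W, U, b, reverse) {
    hs <- matrix(0, n, h)
    hp <- matrix(0, 1L, h); cp <- matrix(0, 1L, h)
    for (t in if (reverse) seq.int(n, 1L) else seq_len(n)) {
      z <- xs[t, , drop = FALSE] %*% W + hp %*% U + b
      ig <- 1 / (1 + exp(-z[, 1:h, drop = FALSE]))
      fg <- 1 / (1 + exp(-z[, (h + 1):(2 * h), drop = FALSE]))
      og <- 1 / (1 + exp(-z[, (2 * h + 1):(3 * h), drop = FALSE]))
      gg <- tanh(z[, (3 * h + 1):(4 * h), drop = FALSE])
      cp <- fg * cp + ig * gg
      hp <- og * tanh(cp)
      hs[t, ] <- hp
    }
    hs
  }
  H <- cbind(run(w$Wf, w$Uf, w$bf, FALSE), run(w$Wb, w$Ub, w$bb, TRUE))
  emis <- sweep(H %*% w$Wo, 2L, as.numeric(w$bo), `+`)
  emis[, 1L] <- emis[, 1L] - 1e6  # PAD column
  emis
}

#' Predict BIO label sequences with a trained BiLSTM-CRF
#'
#' Runs the encoder (no dropout) and decodes each sentence exactly with
#' Viterbi over the learned CRF. Output lengths equal input token counts.
#'
#' @param object A trained `nsc_bilstm_crf`.
#' @param sentences A list of annotated sentences or of character vectors
#'   of tokens. Unknown tokens map to `UNK`.
#' @param ... Unused.
#' @return A list of character label vectors.
#' @export
predict.nsc_bilstm_crf <- function(object, sentences, ...) {
  if (is.null(object$dt)) stop("model carries no token dictionary")
  w <- object$weights
  h <- object$cfg$hidden
  K <- object$alphabet$size
  cp <- crf_params(K, w$trans, as.numeric(w$start), as.numeric(w$end))
  lapply(sentences, function(s) {
    toks <- if (is.character(s)) s else s$tokens$text
    if (length(toks) == 0L) return(character(0))
    ids <- token_ids(object$dt, toks) + 1L
    emis <- bilstm_numeric_emissions(w, ids, h, K)
    id_to_label(object$alphabet, crf_viterbi(emis, cp)$path - 1L)
  })
}

#' @export
print.nsc_bilstm_crf <- function(x, ...) {
  cat(sprintf(
    "<nsc_bilstm_crf> hidden %d, dim %d, |alphabet| %d, %d epochs (final loss %.4f)\n",
    x$cfg$hidden, x$dim, x$alphabet$size, length(x$loss_trace),
    utils::tail(x$loss_trace, 1L)))
  invisible(x)
}
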