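# Minimal reverse-mode automatic differentiation over dense matrices,
# written for the taggers in this package. A tape records nodes in
# creation order; backward() replays it in reverse. Values and gradients
# are plain R matrices. Trainable parameters live outside the tape in
# `nsc_param` environments whose $grad accumulates across sentences of a
# minibatch. Internal API (not exported).

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_push <- function(tape, value, backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backfn <- backfn
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", n))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

ad_const <- function(tape, x) ad_push(tape, x)

# Trainable parameter: persistent value + accumulated gradient + Adam state.
nsc_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- array(0, dim = dim(value) %||% length(value))
  p$m <- p$grad
  p$v <- p$grad
  class(p) <- "nsc_param"
  p
}

ad_leaf <- function(tape, param) {
  nd <- ad_push(tape, param$value)
  nd$backfn <- function(g) param$grad <- param$grad + g
  nd
}

ad_backward <- function(tape, loss, init = 1) {
  loss$grad <- matrix(init, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

# --- elementary ops ---------------------------------------------------------

ad_matmul <- function(tape, A, B) {
  nd <- ad_push(tape, A$value %*% B$value)
  nd$backfn <- function(g) {
    ad_accum(A, g %*% t(B$value))
    ad_accum(B, t(A$value) %*% g)
  }
  nd
}

# A %*% t(B)
ad_matmul_tB <- function(tape, A, B) {
  nd <- ad_push(tape, tcrossprod(A$value, B$value))
  nd$backfn <- function(g) {
    ad_accum(A, g %*% B$value)
    ad_accum(B, t(g) %*% A$value)
  }
  nd
}

# A + B, where B may be a 1 x k bias row broadcast over the rows of A
ad_add <- function(tape, A, B) {
  bias <- nrow(B$value) == 1L && nrow(A$value) > 1L
  v <- if (bias) sweep(A$value, 2L, as.numeric(B$value), `+`) else
    A$value + B$value
  nd <- ad_push(tape, v)
  nd$backfn <- function(g) {
    ad_accum(A, g)
    ad_accum(B, if (bias) matrix(colSums(g), 1L) else g)
  }
  nd
}

ad_mul <- function(tape, A, B) {
  nd <- ad_push(tape, A$value * B$value)
  nd$backfn <- function(g) {
    ad_accum(A, g * B$value)
    ad_accum(B, g * A$value)
  }
  nd
}

# multiply by a constant matrix/scalar (no gradient to the constant)
ad_cmul <- function(tape, A, k) {
  nd <- ad_push(tape, A$value * k)
  nd$backfn <- function(g) ad_accum(A, g * k)
  nd
}

# add a constant matrix (e.g. a -1e6 mask); no gradient to the constant
ad_cadd <- function(tape, A, k) {
  nd <- ad_push(tape, A$value + k)
  nd$backfn <- function(g) ad_accum(A, g)
  nd
}

ad_tanh <- function(tape, A) {
  v <- tanh(A$value)
  nd <- ad_push(tape, v)
  nd$backfn <- function(g) ad_accum(A, g * (1 - v * v))
  nd
}

ad_sigmoid <- function(tape, A) {
  v <- 1 / (1 + exp(-A$value))
  nd <- ad_push(tape, v)
  nd$backfn <- function(g) ad_accum(A, g * v * (1 - v))
  nd
}

ad_relu <- function(tape, A) {
  v <- pmax(A$value, 0)
  nd <- ad_push(tape, v)
  nd$backfn <- function(g) ad_accum(A, g * (A$value > 0))
  nd
}

# row selection with scatter-add backward (embedding lookup)
ad_rows <- function(tape, A, idx) {
  nd <- ad_push(tape, A$value[idx, , drop = FALSE])
  nd$backfn <- function(g) {
    gA <- matrix(0, nrow(A$value), ncol(A$value))
    agg <- rowsum(g, group = idx)
    gA[as.integer(rownames(agg)), ] <- agg
    ad_accum(A, gA)
  }
  nd
}

ad_cols <- function(tape, A, range) {
  nd <- ad_push(tape, A$value[, range, drop = FALSE])
  nd$backfn <- function(g) {
    gA <- matrix(0, nrow(A$value), ncol(A$value))
    gA[, range] <- g
    ad_accum(A, gA)
  }
  nd
}

# stack 1 x k row nodes into an n x k matrix
ad_vconcat <- function(tape, rows) {
  nd <- ad_push(tape, do.call(rbind, lapply(rows, `[[`, "value")))
  nd$backfn <- function(g) {
    for (i in seq_along(rows)) ad_accum(rows[[i]], g[i, , drop = FALSE])
  }
  nd
}

ad_hconcat <- function(tape, A, B) {
  ka <- ncol(A$value)
  nd <- ad_push(tape, cbind(A$value, B$value))
  nd$backfn <- function(g) {
    ad_accum(A, g[, seq_len(ka), drop = FALSE])
    ad_accum(B, g[, -seq_len(ka), drop = FALSE])
  }
  nd
}

ad_softmax_rows <- function(tape, A) {
  z <- A$value - apply(A$value, 1L, max)
  e <- exp(z)
  P <- e / rowSums(e)
  nd <- ad_push(tape, P)
  nd$backfn <- function(g) {
    ad_accum(A, (g - rowSums(g * P)) * P)
  }
  nd
}

# row-wise layer normalization with learned gain/bias (1 x k each)
ad_layernorm <- function(tape, A, gain, bias, eps = 1e-5) {
  x <- A$value
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  sd_ <- sqrt(va + eps)
  xhat <- xc / sd_
  v <- sweep(sweep(xhat, 2L, as.numeric(gain$value), `*`),
             2L, as.numeric(bias$value), `+`)
  nd <- ad_push(tape, v)
  nd$backfn <- function(g) {
    dxhat <- sweep(g, 2L, as.numeric(gain$value), `*`)
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd_
    ad_accum(A, dx)
    ad_accum(gain, matrix(colSums(g * xhat), 1L))
    ad_accum(bias, matrix(colSums(g), 1L))
  }
  nd
}

# weighted mean cross-entropy over rows of a logit matrix.
# targets: 1-based column index per row; weights: per-row (0 masks a row).
ad_mean_xent <- function(tape, logits, targets, weights) {
  z <- logits$value - apply(logits$value, 1L, max)
  e <- exp(z)
  P <- e / rowSums(e)
  wsum <- sum(weights)
  if (wsum <= 0) stop("all rows masked in cross-entropy")
  picked <- P[cbind(seq_along(targets), targets)]
  loss <- sum(weights * (-log(pmax(picked, 1e-300)))) / wsum
  nd <- ad_push(tape, matrix(loss, 1L, 1L))
  nd$backfn <- function(g) {
    Y <- matrix(0, nrow(P), ncol(P))
    Y[cbind(seq_along(targets), targets)] <- 1
    ad_accum(logits, as.numeric(g) * (P - Y) * (weights / wsum))
  }
  nd
}

# linear-chain CRF negative log-likelihood as a fused op. Gradients are
# expected-minus-observed sufficient statistics from forward-backward.
ad_crf_nll <- function(tape, emissions, transitions, start, end, gold) {
  em <- emissions$value
  tr <- transitions$value
  st <- as.numeric(start$value)
  en <- as.numeric(end$value)
  fb <- crf_forward_backward(em, tr, st, en)
  n <- nrow(em)
  score <- st[gold[1L]] + sum(em[cbind(seq_len(n), gold)]) + en[gold[n]] +
    if (n > 1L) sum(tr[cbind(gold[-n], gold[-1L])]) else 0
  nd <- ad_push(tape, matrix(fb$logZ - score, 1L, 1L))
  nd$backfn <- function(g) {
    gs <- as.numeric(g)
    dem <- fb$unary
    dem[cbind(seq_len(n), gold)] <- dem[cbind(seq_len(n), gold)] - 1
    dtr <- fb$pairwise
    if (n > 1L) {
      idx <- cbind(gold[-n], gold[-1L])
      for (r in seq_len(nrow(idx))) dtr[idx[r, 1L], idx[r, 2L]] <-
          dtr[idx[r, 1L], idx[r, 2L]] - 1
    }
    dst <- fb$unary[1L, ]; dst[gold[1L]] <- dst[gold[1L]] - 1
    den <- fb$unary[n, ]; den[gold[n]] <- den[gold[n]] - 1
    ad_accum(emissions, gs * dem)
    ad_accum(transitions, gs * dtr)
    ad_accum(start, matrix(gs * dst, 1L))
    ad_accum(end, matrix(gs * den, 1L))
  }
  nd
}

# add a gathered bias to a matrix: value = A + vec[idx], with scatter-add
# backward into the bias vector (relative-position attention biases)
ad_add_gather <- function(tape, A, vec, idx) {
  v <- A$value + matrix(vec$value[idx], nrow(A$value), ncol(A$value))
  nd <- ad_push(tape, v)
  nd$backfn <- function(g) {
    ad_accum(A, g)
    gv <- matrix(0, 1L, length(vec$value))
    agg <- rowsum(as.numeric(g), group = as.integer(idx))
    gv[as.integer(rownames(agg))] <- agg
    ad_accum(vec, gv)
  }
  nd
}

# --- optimizer --------------------------------------------------------------

adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  if (!is.null(clip)) {
    total <- sqrt(sum(vapply(params, function(p) sum(p$grad^2), 0)))
    if (is.finite(total) && total > clip) {
      sc <- clip / total
      for (p in params) p$grad <- p$grad * sc
    }
  }
  for (p in params) {
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}

# numerical gradient of scalar f(value) for gradient-check tests
numeric_grad <- function(f, value, h = 1e-5) {
  g <- array(0, dim = dim(value) %||% length(value))
  for (i in seq_along(value)) {
    vp <- value; vp[i] <- vp[i] + h
    vm <- value; vm[i] <- vm[i] - h
    g[i] <- (f(vp) - f(vm)) / (2 * h)
  }
  g
}
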