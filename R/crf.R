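# Linear-chain conditional random field: exact Viterbi decoding and the
# forward algorithm in log space. The chain score of a label path y over
# emissions e is start(y1) + sum_t e[t, yt] + sum_t trans[yt, yt+1] +
# end(yn).

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' CRF parameter container
#'
#' @param K Number of labels.
#' @param transitions `K x K` matrix: score of label `u` (row) followed by
#'   label `v` (column).
#' @param start,end Length-`K` vectors of start/end transition scores.
#' @return An object of class `nsc_crf_params`.
#' @export
crf_params <- function(K, transitions = matrix(0, K, K),
                       start = numeric(K), end = numeric(K)) {
  stopifnot(nrow(transitions) == K, ncol(transitions) == K,
            length(start) == K, length(end) == K,
            all(is.finite(transitions) | transitions < 0))
  structure(list(K = K, transitions = transitions, start = start, end = end),
            class = "nsc_crf_params")
}

#' Exact Viterbi decoding of a linear-chain CRF
#'
#' Returns the label path maximizing
#' `start(y1) + sum(emissions[t, y_t]) + sum(transitions[y_t, y_t+1]) +
#' end(y_n)` over all `K^n` paths. Ties are broken toward the
#' lexicographically smallest path in label-index order.
#'
#' @param emissions `n x K` matrix of per-token label scores (finite).
#' @param params [crf_params()].
#' @return List with `path` (integer vector of 1-based label indices) and
#'   `score`.
#' @export
crf_viterbi <- function(emissions, params) {
  emissions <- as.matrix(emissions)
  n <- nrow(emissions); K <- ncol(emissions)
  stopifnot(n >= 1L, K == params$K)
  if (!all(is.finite(emissions))) stop("non-finite emissions")
  delta <- matrix(-Inf, n, K)
  psi <- matrix(0L, n, K)
  delta[1L, ] <- params$start + emissions[1L, ]
  if (n > 1L) for (t in 2L:n) {
    for (v in seq_len(K)) {
      cand <- delta[t - 1L, ] + params$transitions[, v]
      b <- which.max(cand)        # first max = smallest label index
      psi[t, v] <- b
      delta[t, v] <- cand[b] + emissions[t, v]
    }
  }
  final <- delta[n, ] + params$end
  path <- integer(n)
  path[n] <- which.max(final)
  if (n > 1L) for (t in (n - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  list(path = path, score = final[path[n]])
}

# forward-backward in log space; returns logZ plus unary and (summed)
# pairwise marginals, the sufficient statistics for the NLL gradient.
crf_forward_backward <- function(emissions, transitions, start, end) {
  n <- nrow(emissions); K <- ncol(emissions)
  alpha <- matrix(-Inf, n, K)
  alpha[1L, ] <- start + emissions[1L, ]
  if (n > 1L) for (t in 2L:n)
    for (v in seq_len(K))
      alpha[t, v] <- logsumexp(alpha[t - 1L, ] + transitions[, v]) +
        emissions[t, v]
  logZ <- logsumexp(alpha[n, ] + end)
  beta <- matrix(-Inf, n, K)
  beta[n, ] <- end
  if (n > 1L) for (t in (n - 1L):1L)
    for (u in seq_len(K))
      beta[t, u] <- logsumexp(transitions[u, ] + emissions[t + 1L, ] +
                                beta[t + 1L, ])
  unary <- exp(alpha + beta - logZ)
  pairwise <- matrix(0, K, K)
  if (n > 1L) for (t in seq_len(n - 1L)) {
    lp <- outer(alpha[t, ], rep(1, K)) + transitions +
      outer(rep(1, K), emissions[t + 1L, ] + beta[t + 1L, ]) - logZ
    pairwise <- pairwise + exp(lp)
  }
  list(logZ = logZ, unary = unary, pairwise = pairwise)
}

#' Negative log-likelihood of a gold path under a linear-chain CRF
#'
#' `log Z - score(gold)`, with the partition function `log Z` computed by
#' the forward algorithm in log space. Always non-negative.
#'
#' @inheritParams crf_viterbi
#' @param gold_path Integer vector of 1-based label indices, length `n`.
#' @return A non-negative scalar.
#' @export
crf_nll <- function(emissions, params, gold_path) {
  emissions <- as.matrix(emissions)
  n <- nrow(emissions); K <- ncol(emissions)
  stopifnot(K == params$K)
  if (length(gold_path) != n || any(gold_path < 1L | gold_path > K))
    stop("invalid gold path: must be ", n, " label indices in 1..", K)
  if (!all(is.finite(emissions))) stop("non-finite emissions")
  fb <- crf_forward_backward(emissions, params$transitions, params$start,
                             params$end)
  score <- params$start[gold_path[1L]] +
    sum(emissions[cbind(seq_len(n), gold_path)]) +
    params$end[gold_path[n]] +
    if (n > 1L) sum(params$transitions[cbind(gold_path[-n],
                                             gold_path[-1L])]) else 0
  fb$logZ - score
}

# brute-force path enumeration; independent oracle used by the tests
crf_enumerate <- function(emissions, params) {
  n <- nrow(emissions); K <- ncol(emissions)
  paths <- as.matrix(expand.grid(rev(replicate(n, seq_len(K),
                                               simplify = FALSE))))
  paths <- paths[, rev(seq_len(n)), drop = FALSE]  # column t = y_t
  scores <- params$start[paths[, 1L]] + params$end[paths[, n]]
  for (t in seq_len(n)) scores <- scores + emissions[t, paths[, t]]
  if (n > 1L) for (t in seq_len(n - 1L))
    scores <- scores + params$transitions[cbind(paths[, t], paths[, t + 1L])]
  ord <- do.call(order, c(list(-scores), lapply(seq_len(n),
                                                function(t) paths[, t])))
  best <- ord[1L]
  list(path = as.integer(paths[best, ]), score = scores[best],
       logZ = logsumexp(scores))
}
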