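# BIO sequence encoding: annotated sentences -> label sequences and the
# padded token/label matrix bundle (T, L, T', L', H); inverse decoding of
# predicted label sequences into cue/scope entities.

#' The fixed BIO label alphabet
#'
#' Ten labels: `PAD`, `O`, and B-/I- pairs for negation cue (`NEG`),
#' negation scope (`NSCO`), uncertainty cue (`UNC`) and uncertainty scope
#' (`USCO`). `PAD` has reserved id 0 and `O` id 1; ids are dense. A
#' negation-only restriction (6 labels) is used for corpora without
#' uncertainty annotations.
#'
#' @param kinds Character vector, subset of `c("negation", "uncertainty")`.
#' @return An object of class `nsc_alphabet` with fields `labels`
#'   (ordered character vector), `to_id` (named integer vector of 0-based
#'   ids) and `size`.
#' @export
label_alphabet <- function(kinds = c("negation", "uncertainty")) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  labels <- c("PAD", "O")
  if ("negation" %in% kinds)
    labels <- c(labels, "B-NEG", "I-NEG", "B-NSCO", "I-NSCO")
  if ("uncertainty" %in% kinds)
    labels <- c(labels, "B-UNC", "I-UNC", "B-USCO", "I-USCO")
  ids <- stats::setNames(seq_along(labels) - 1L, labels)
  structure(list(labels = labels, to_id = ids, size = length(labels)),
            class = "nsc_alphabet")
}

#' Map labels to 0-based ids and back
#' @param alphabet An `nsc_alphabet`.
#' @param labels Character vector of labels.
#' @return Integer vector of 0-based ids.
#' @export
label_to_id <- function(alphabet, labels) {
  ids <- alphabet$to_id[labels]
  if (anyNA(ids)) stop("unknown label(s): ",
                       paste(unique(labels[is.na(ids)]), collapse = ", "))
  unname(ids)
}

#' @rdname label_to_id
#' @param ids Integer vector of 0-based ids.
#' @export
id_to_label <- function(alphabet, ids) {
  if (any(ids < 0L | ids >= alphabet$size)) stop("label id out of range")
  alphabet$labels[ids + 1L]
}

# category name ("NEG", "NSCO", "UNC", "USCO") for (kind, role)
category_of <- function(kind, role) {
  switch(paste(kind, role),
         "negation cue" = "NEG", "negation scope" = "NSCO",
         "uncertainty cue" = "UNC", "uncertainty scope" = "USCO",
         stop("unknown kind/role: ", kind, "/", role))
}

# token indices (1-based) covered by a fragment; partial overlaps snap
# outward to whole tokens
fragment_token_indices <- function(tokens, frag, warn_context = NULL) {
  hit <- which(tokens$char_start < frag$char_end &
                 tokens$char_end > frag$char_start)
  if (length(hit) > 0L && !is.null(warn_context)) {
    lo <- tokens[hit[1L], ]; hi <- tokens[hit[length(hit)], ]
    if (lo$char_start < frag$char_start || hi$char_end > frag$char_end)
      warning("fragment [", frag$char_start, ",", frag$char_end,
              ") of ", warn_context,
              " is not token-aligned; snapped outward", call. = FALSE)
  }
  hit
}

#' Convert an annotated sentence to a BIO label sequence
#'
#' Per annotation fragment, the first covered token receives `B-` and
#' subsequent tokens `I-`, with the category chosen by kind (negation /
#' uncertainty) and role (cue / scope); each fragment of a discontinuous
#' annotation restarts its own `B-` run; unannotated tokens are `O`. When
#' one token is claimed by two annotations the precedence is cue over
#' scope, then negation over uncertainty (conflicts are logged).
#'
#' @param sentence An [annotated_sentence()].
#' @param alphabet A [label_alphabet()].
#' @return Character vector of labels, aligned 1:1 with the sentence's
#'   tokens.
#' @export
to_bio <- function(sentence, alphabet = label_alphabet()) {
  n <- nrow(sentence$tokens)
  labels <- rep("O", n)
  # priority: larger wins a token. cue > scope, negation > uncertainty.
  prio_of <- c(NEG = 4L, UNC = 3L, NSCO = 2L, USCO = 1L)
  prio <- rep(0L, n)
  anns <- c(lapply(sentence$cues, function(a) list(a = a, role = "cue")),
            lapply(sentence$scopes, function(a) list(a = a, role = "scope")))
  for (entry in anns) {
    cat_ <- category_of(entry$a$kind, entry$role)
    if (!paste0("B-", cat_) %in% alphabet$labels)
      stop("alphabet lacks labels for category ", cat_)
    p <- prio_of[[cat_]]
    for (fi in seq_len(nrow(entry$a$fragments))) {
      idx <- fragment_token_indices(sentence$tokens,
                                    entry$a$fragments[fi, ],
                                    warn_context = entry$a$id)
      idx <- idx[order(idx)]
      first <- TRUE
      for (t in idx) {
        if (prio[t] >= p) {
          if (prio[t] > 0L)
            nsc_log("label conflict at token ", t, " of ",
                    dQuote(sentence$text), "; keeping ", labels[t],
                    level = "debug")
          next
        }
        labels[t] <- paste0(if (first) "B-" else "I-", cat_)
        prio[t] <- p
        first <- FALSE
      }
    }
  }
  labels
}

#' Build the token dictionary and label alphabet of a corpus
#'
#' The token dictionary maps every distinct token of the corpus to a dense
#' integer id, with reserved ids `PAD = 0` and `UNK = 1`. The label
#' alphabet is the fixed 10-label set, restricted to its negation-only
#' 6-label form when the corpus has no uncertainty annotations.
#'
#' @param corpus Non-empty list of annotated sentences.
#' @return List with elements `dt` (class `nsc_token_dict`: fields
#'   `to_id` named 0-based ids, `tokens`, `pad_id = 0`, `unk_id = 1`) and
#'   `alphabet`.
#' @export
build_dictionaries <- function(corpus) {
  if (length(corpus) == 0L) stop("corpus is empty")
  toks <- unique(unlist(lapply(corpus, function(s) s$tokens$text),
                        use.names = FALSE))
  to_id <- stats::setNames(seq_along(toks) + 1L, toks)  # 0=PAD, 1=UNK
  dt <- structure(list(to_id = to_id, tokens = toks,
                       pad_id = 0L, unk_id = 1L,
                       size = length(toks) + 2L),
                  class = "nsc_token_dict")
  any_unc <- any(vapply(corpus, function(s)
    any(vapply(s$cues, function(c) c$kind == "uncertainty", NA)) ||
      any(vapply(s$scopes, function(c) c$kind == "uncertainty", NA)),
    NA))
  alphabet <- if (any_unc) label_alphabet() else label_alphabet("negation")
  list(dt = dt, alphabet = alphabet)
}

token_ids <- function(dt, tokens) {
  ids <- dt$to_id[tokens]
  ids[is.na(ids)] <- dt$unk_id
  unname(ids)
}

#' Serialize / read a token dictionary as JSON
#' @param dt An `nsc_token_dict`.
#' @param path File path.
#' @export
write_token_dict <- function(dt, path) {
  jsonlite::write_json(list(format_version = 1L,
                            pad_id = dt$pad_id, unk_id = dt$unk_id,
                            tokens = as.list(dt$to_id)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_token_dict
#' @export
read_token_dict <- function(path) {
  o <- jsonlite::fromJSON(path)
  to_id <- unlist(o$tokens)
  structure(list(to_id = to_id, tokens = names(to_id),
                 pad_id = o$pad_id, unk_id = o$unk_id,
                 size = length(to_id) + 2L),
            class = "nsc_token_dict")
}

#' Encode a corpus into the padded matrix bundle
#'
#' Builds the five aligned structures used by the taggers: `T` (token
#' strings, one sentence per row), `L` (BIO labels), `Tp`/`Lp` (their
#' dictionary codifications) and `H` (one-hot array of `Lp`,
#' `i x j x |alphabet|`). Positions beyond a sentence's length hold `PAD`
#' in all five; tokens absent from the dictionary map to `UNK`.
#'
#' @param corpus List of annotated sentences.
#' @param dt Token dictionary from [build_dictionaries()].
#' @param alphabet Label alphabet.
#' @param j Padded row length; defaults to the longest sentence. Must be
#'   at least the longest sentence unless `truncate = TRUE`.
#' @param truncate Allow silently truncating over-long sentences.
#' @return An object of class `nsc_encoded_batch` with fields `T`, `L`,
#'   `Tp`, `Lp`, `H`, `lengths`, `i`, `j`.
#' @export
encode_matrices <- function(corpus, dt, alphabet = label_alphabet(),
                            j = NULL, truncate = FALSE) {
  i <- length(corpus)
  lens <- vapply(corpus, function(s) nrow(s$tokens), 0L)
  j <- as.integer(j %||% max(lens, 1L))
  if (!truncate && any(lens > j)) {
    k <- which(lens > j)[1L]
    stop("sentence ", k, " (", dQuote(corpus[[k]]$text), ") has ", lens[k],
         " tokens > j = ", j, "; enable truncate or raise j")
  }
  K <- alphabet$size
  Tm <- matrix("PAD", i, j); Lm <- matrix("PAD", i, j)
  Tp <- matrix(dt$pad_id, i, j); Lp <- matrix(0L, i, j)
  H <- array(0, dim = c(i, j, K))
  for (s in seq_len(i)) {
    n <- min(lens[s], j)
    if (n > 0L) {
      toks <- corpus[[s]]$tokens$text[seq_len(n)]
      labs <- to_bio(corpus[[s]], alphabet)[seq_len(n)]
      Tm[s, seq_len(n)] <- toks
      Lm[s, seq_len(n)] <- labs
      Tp[s, seq_len(n)] <- token_ids(dt, toks)
      Lp[s, seq_len(n)] <- label_to_id(alphabet, labs)
    }
  }
  for (s in seq_len(i)) for (t in seq_len(j)) H[s, t, Lp[s, t] + 1L] <- 1
  structure(list(T = Tm, L = Lm, Tp = Tp, Lp = Lp, H = H,
                 lengths = pmin(lens, j), i = i, j = j,
                 alphabet = alphabet),
            class = "nsc_encoded_batch")
}

#' @export
print.nsc_encoded_batch <- function(x, ...) {
  cat(sprintf("<nsc_encoded_batch> %d sentences x %d positions, |alphabet| = %d\n",
              x$i, x$j, x$alphabet$size))
  invisible(x)
}

#' Decode a BIO label sequence into entities
#'
#' Maximal runs `B-X (I-X)*` become one entity of category `X`; an `I-X`
#' without an open `X` run is repaired to `B-X` (logged). Inverse of
#' [to_bio()] at fragment level.
#'
#' @param labels Character vector of BIO labels (no `PAD`).
#' @param tokens Optional token table (for span reporting).
#' @return A list of entities, each `list(category, kind, role,
#'   token_indices)` with 1-based token indices, in token order.
#' @export
decode_entities <- function(labels, tokens = NULL) {
  if (any(labels == "PAD")) stop("PAD labels must be stripped before decoding")
  ents <- list()
  open_cat <- NULL; open_idx <- integer()
  flush <- function() {
    if (!is.null(open_cat)) {
      kind <- if (open_cat %in% c("NEG", "NSCO")) "negation" else "uncertainty"
      role <- if (open_cat %in% c("NEG", "UNC")) "cue" else "scope"
      ents[[length(ents) + 1L]] <<- list(category = open_cat, kind = kind,
                                         role = role, token_indices = open_idx)
    }
    open_cat <<- NULL; open_idx <<- integer()
  }
  for (t in seq_along(labels)) {
    lab <- labels[t]
    if (lab == "O") { flush(); next }
    pre <- substr(lab, 1L, 1L)
    cat_ <- substr(lab, 3L, nchar(lab))
    if (pre == "B" || is.null(open_cat) || cat_ != open_cat) {
      if (pre == "I" && (is.null(open_cat) || cat_ != open_cat))
        nsc_log("I-", cat_, " without open run at token ", t,
                "; repaired to B-", cat_, level = "debug")
      flush()
      open_cat <- cat_; open_idx <- t
    } else {
      open_idx <- c(open_idx, t)
    }
  }
  flush()
  ents
}

# ---------------------------------------------------------------------------
# CoNLL-style TSV: token<TAB>gold<TAB>pred, blank line between sentences.

#' Write gold (and optionally predicted) label sequences as CoNLL-style TSV
#'
#' @param corpus List of annotated sentences (or a list of character
#'   vectors of tokens).
#' @param gold List of gold label sequences.
#' @param pred Optional list of predicted label sequences.
#' @param path Output file.
#' @export
write_conll <- function(corpus, gold, pred = NULL, path) {
  stopifnot(length(corpus) == length(gold),
            is.null(pred) || length(pred) == length(gold))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in seq_along(corpus)) {
    toks <- if (is.character(corpus[[s]])) corpus[[s]] else
      corpus[[s]]$tokens$text
    stopifnot(length(toks) == length(gold[[s]]))
    lines <- if (is.null(pred)) paste(toks, gold[[s]], sep = "\t") else
      paste(toks, gold[[s]], pred[[s]], sep = "\t")
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}

#' Read a CoNLL-style TSV written by [write_conll()]
#' @param path Input file.
#' @return List with `tokens`, `gold` and (when present) `pred`, each a
#'   list of per-sentence character vectors.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sent_id <- cumsum(c(TRUE, !nzchar(lines[-length(lines)])))
  keep <- nzchar(lines)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol <- unique(lengths(parts))
  if (length(ncol) != 1L) stop("ragged CoNLL file: ", path)
  by_sent <- split(parts, sent_id[keep])
  res <- list(
    tokens = lapply(by_sent, function(p) vapply(p, `[`, "", 1L)),
    gold = lapply(by_sent, function(p) vapply(p, `[`, "", 2L))
  )
  if (ncol >= 3L)
    res$pred <- lapply(by_sent, function(p) vapply(p, `[`, "", 3L))
  res <- lapply(res, unname)
  res
}
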