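# Synthetic Spanish-like clinical corpus generator. Emulates the
# distributional structure of the public clinical corpora (sentence-length
# quantiles, fraction of negated/uncertain sentences, cue inventories and
# class mix, continuous/discontinuous scope shares, scope side relative to
# the cue) without any claim to grammaticality: only the statistical
# structure matters for exercising the pipeline.

#' Build a cue inventory table
#'
#' @param surface Cue surfaces (may be multi-token, space separated).
#' @param class Cue class per surface: `"syntactic"`, `"lexical"` or
#'   `"morphological"`.
#' @param freq Relative frequency per surface (normalized to sum 1).
#' @param dir_right,dir_left,dir_both Scope-direction distribution per
#'   surface (each row normalized to sum 1).
#' @export
cue_inventory <- function(surface, class, freq, dir_right = 0.85,
                          dir_left = 0.05, dir_both = 0.10) {
  d <- data.frame(surface = surface, class = class, freq = freq,
                  dir_right = dir_right, dir_left = dir_left,
                  dir_both = dir_both, stringsAsFactors = FALSE)
  stopifnot(all(d$class %in% c("syntactic", "lexical", "morphological")),
            all(d$freq > 0))
  d$freq <- d$freq / sum(d$freq)
  dsum <- d$dir_right + d$dir_left + d$dir_both
  d$dir_right <- d$dir_right / dsum
  d$dir_left <- d$dir_left / dsum
  d$dir_both <- d$dir_both / dsum
  d
}

#' Generator configuration
#'
#' Distributional knobs the synthetic corpus honors. See
#' [default_config_nubeslike()] for the defaults that emulate the large
#' public clinical corpus.
#'
#' @param p_negated,p_uncertain Sentence-level probabilities of carrying a
#'   negation / uncertainty annotation.
#' @param negation_cues,uncertainty_cues [cue_inventory()] tables.
#' @param p_continuous Probability that a scope is a single fragment.
#' @param length_quantiles Target `(q1, median, q3)` token counts; a
#'   log-normal is fitted to these.
#' @param filler_vocabulary Neutral clinical tokens (must be disjoint from
#'   cue surfaces).
#' @param p_multi_cue Probability of one extra cue in an annotated
#'   sentence.
#' @param scope_extent `"sampled"` (scope length drawn ~ 1 + Poisson(2)) or
#'   `"full"` (scope runs to the sentence edge on its side; at most one
#'   annotation per sentence, used for separable learnability corpora).
#' @param seed Default seed recorded in the config.
#' @return Object of class `nsc_generator_config`.
#' @export
generator_config <- function(p_negated, p_uncertain, negation_cues,
                             uncertainty_cues, p_continuous,
                             length_quantiles, filler_vocabulary,
                             p_multi_cue = 0.15,
                             scope_extent = c("sampled", "full"),
                             seed = 13L) {
  scope_extent <- match.arg(scope_extent)
  probs <- c(p_negated, p_uncertain, p_continuous, p_multi_cue)
  stopifnot(all(probs >= 0 & probs <= 1),
            length(length_quantiles) == 3L,
            length_quantiles[1] <= length_quantiles[2],
            length_quantiles[2] <= length_quantiles[3])
  cue_surf <- unlist(strsplit(c(negation_cues$surface,
                                uncertainty_cues$surface), " ", fixed = TRUE))
  if (any(filler_vocabulary %in% cue_surf))
    stop("filler vocabulary overlaps cue surfaces: ",
         paste(intersect(filler_vocabulary, cue_surf), collapse = ", "))
  structure(list(p_negated = p_negated, p_uncertain = p_uncertain,
                 negation_cues = negation_cues,
                 uncertainty_cues = uncertainty_cues,
                 p_continuous = p_continuous,
                 length_quantiles = as.numeric(length_quantiles),
                 filler_vocabulary = filler_vocabulary,
                 p_multi_cue = p_multi_cue, scope_extent = scope_extent,
                 seed = as.integer(seed)),
            class = "nsc_generator_config")
}

nsc_filler_vocabulary <- c(
  "paciente", "presenta", "refiere", "dolor", "abdominal", "fiebre", "tos",
  "disnea", "cefalea", "nauseas", "vomitos", "exploracion", "abdomen",
  "blando", "depresible", "analitica", "normal", "radiografia", "torax",
  "lesiones", "hallazgos", "signos", "derrame", "pleural", "edemas",
  "adenopatias", "soplos", "molestias", "tratamiento", "control",
  "evolucion", "favorable", "afectacion", "hepatica", "masa", "pulmonar",
  "izquierdo", "derecho", "leve", "aguda", "cronica", "secundaria",
  "durante", "ingreso", "alta", "consulta", "actual", "previa")

#' Default generator configuration emulating the large public corpus
#'
#' Fractions of negated (25.5%) and uncertain (7.5%) sentences, 95%
#' continuous scopes, sentence-length quantiles (9, 14, 23), and cue
#' inventories whose five most frequent negation surfaces
#' ("no, sin, negativo, negativos, niega") carry 87% of the negation mass
#' while the five most frequent uncertainty surfaces carry just under 48%.
#' The cue class mix is 85/6/9 (syntactic/lexical/morphological) for
#' negation and 2/98 (syntactic/lexical) for uncertainty.
#'
#' @return An `nsc_generator_config`.
#' @export
default_config_nubeslike <- function() {
  neg <- cue_inventory(
    surface = c("no", "sin", "negativo", "negativos", "niega",
                "nunca", "tampoco", "ausencia de",
                "afebril", "asintomatico", "anicterico", "apiretico",
                "indoloro", "acelular"),
    class = c("syntactic", "syntactic", "lexical", "lexical", "lexical",
              "syntactic", "syntactic", "syntactic",
              rep("morphological", 6L)),
    freq = c(0.55, 0.26, 0.022, 0.02, 0.018,
             0.016, 0.014, 0.010,
             rep(0.015, 6L)),
    dir_right = c(0.85, 0.85, 0.10, 0.10, 0.90,
                  0.85, 0.85, 0.85, rep(1, 6L)),
    dir_left = c(0.05, 0.05, 0.80, 0.80, 0.05,
                 0.05, 0.05, 0.05, rep(0, 6L)),
    dir_both = c(0.10, 0.10, 0.10, 0.10, 0.05,
                 0.10, 0.10, 0.10, rep(0, 6L)))
  unc <- cue_inventory(
    surface = c("probable", "posible", "compatible con", "sospecha de",
                "parece", "sugiere", "sugestivo de", "impresiona",
                "dudoso", "aparente", "pendiente de confirmar",
                "probablemente", "podria", "quizas", "valorar",
                "o", "versus", "vs"),
    class = c(rep("lexical", 15L), rep("syntactic", 3L)),
    freq = c(0.12, 0.11, 0.09, 0.08, 0.07,
             0.07, 0.06, 0.06, 0.06, 0.05, 0.05, 0.05, 0.04, 0.04, 0.03,
             0.01, 0.005, 0.005),
    dir_right = c(rep(0.70, 15L), rep(0.10, 3L)),
    dir_left = c(rep(0.20, 15L), rep(0.10, 3L)),
    dir_both = c(rep(0.10, 15L), rep(0.80, 3L)))
  generator_config(
    p_negated = 0.255, p_uncertain = 0.075,
    negation_cues = neg, uncertainty_cues = unc,
    p_continuous = 0.95, length_quantiles = c(9, 14, 23),
    filler_vocabulary = nsc_filler_vocabulary,
    p_multi_cue = 0.15, scope_extent = "sampled", seed = 13L)
}

#' Separable generator configuration for learnability checks
#'
#' Cue vocabulary disjoint from the filler vocabulary, all scopes
#' continuous and running to the sentence edge on their side, at most one
#' annotation per sentence: a corpus whose labeling is a deterministic
#' function of surface cues and position, hence learnable to near-perfect
#' token F1 by a competent tagger.
#'
#' @param p_negated,p_uncertain Sentence-level annotation probabilities.
#' @return An `nsc_generator_config`.
#' @export
config_separable <- function(p_negated = 0.5, p_uncertain = 0.3) {
  neg <- cue_inventory(
    surface = c("no", "sin", "niega", "negativo"),
    class = c("syntactic", "syntactic", "lexical", "lexical"),
    freq = c(0.4, 0.3, 0.2, 0.1),
    dir_right = c(1, 1, 1, 0), dir_left = c(0, 0, 0, 1), dir_both = 0)
  unc <- cue_inventory(
    surface = c("probable", "posible", "sospecha"),
    class = "lexical", freq = c(0.4, 0.35, 0.25),
    dir_right = 1, dir_left = 0, dir_both = 0)
  generator_config(
    p_negated = p_negated, p_uncertain = p_uncertain,
    negation_cues = neg, uncertainty_cues = unc,
    p_continuous = 1, length_quantiles = c(6, 9, 13),
    filler_vocabulary = nsc_filler_vocabulary,
    p_multi_cue = 0, scope_extent = "full", seed = 13L)
}

# fit log-normal to (q1, median, q3): meanlog = log(median),
# sdlog from the interquartile spread of the log
length_model <- function(q) {
  list(meanlog = log(q[2]),
       sdlog = (log(q[3]) - log(q[1])) / (2 * stats::qnorm(0.75)))
}

#' Generate a synthetic annotated corpus
#'
#' A pure function of `(config, n, seed)`: identical inputs give
#' byte-identical corpora. Sentences are assembled from filler tokens with
#' cue insertions and scope spans on the sampled side(s); gold cue and
#' scope annotations with character offsets are emitted for every
#' insertion. Morphological-negation cues (affixal, e.g. "afebril") carry
#' the negation in the cue token itself and emit no separate scope record.
#'
#' @param config An `nsc_generator_config`.
#' @param n Number of sentences (>= 1).
#' @param seed Integer seed.
#' @param sentences_per_doc Sentences grouped per synthetic document id.
#' @return An `nsc_corpus` list of annotated sentences.
#' @export
generate_corpus <- function(config, n, seed = config$seed,
                            sentences_per_doc = 10L) {
  stopifnot(inherits(config, "nsc_generator_config"))
  if (n < 1L) stop("n must be >= 1")
  with_local_seed(seed, {
    lm <- length_model(config$length_quantiles)
    out <- vector("list", n)
    for (s in seq_len(n)) {
      doc_id <- sprintf("synth%05d", (s - 1L) %/% sentences_per_doc + 1L)
      out[[s]] <- generate_sentence(config, lm, doc_id)
    }
    structure(out, class = "nsc_corpus")
  })
}

generate_sentence <- function(config, lm, doc_id) {
  events <- character()
  if (stats::runif(1) < config$p_negated) events <- c(events, "negation")
  if (stats::runif(1) < config$p_uncertain) events <- c(events, "uncertainty")
  if (config$scope_extent == "full" && length(events) > 1L)
    events <- sample(events, 1L)
  if (length(events) >= 1L && stats::runif(1) < config$p_multi_cue)
    events <- c(events, sample(events, 1L))
  L <- max(3L * max(1L, length(events)),
           round(stats::rlnorm(1, lm$meanlog, lm$sdlog)))
  L <- min(L, 80L)
  fillers <- sample(config$filler_vocabulary, L, replace = TRUE)
  if (length(events) == 0L) {
    return(assemble_sentence(c(fillers, "."), list(), doc_id))
  }
  # split filler into one contiguous segment per event
  e <- length(events)
  cuts <- floor(seq(0L, L, length.out = e + 1L))
  tokens <- character(); anns <- list(); tn <- 0L
  for (k in seq_len(e)) {
    seg <- fillers[(cuts[k] + 1L):cuts[k + 1L]]
    built <- build_event(config, events[k], seg, offset = length(tokens),
                         ann_counter = tn)
    tokens <- c(tokens, built$tokens)
    anns <- c(anns, built$anns)
    tn <- tn + length(built$anns)
  }
  assemble_sentence(c(tokens, "."), anns, doc_id)
}

# Insert one cue (+scope) event into a filler segment. Returns the segment
# token vector with the cue spliced in, plus annotation records as token
# index ranges relative to the full sentence (offset supplied).
build_event <- function(config, kind, seg, offset, ann_counter) {
  inv <- if (kind == "negation") config$negation_cues else
    config$uncertainty_cues
  row <- inv[sample.int(nrow(inv), 1L, prob = inv$freq), ]
  cue_toks <- strsplit(row$surface, " ", fixed = TRUE)[[1]]
  m <- length(seg)
  anns <- list()
  morph <- row$class == "morphological"
  continuous <- morph || stats::runif(1) < config$p_continuous
  # direction: continuous scopes sit on one side (right/left, renormalized);
  # discontinuous scopes surround the cue (the field's canonical example)
  # or, when the cue never takes both sides, split one side with a gap.
  if (continuous) {
    pr <- c(row$dir_right, row$dir_left)
    dir <- if (sum(pr) <= 0) "right" else
      sample(c("right", "left"), 1L, prob = pr)
  } else {
    dir <- if (row$dir_both > 0) "both" else
      if (row$dir_right >= row$dir_left) "gap_right" else "gap_left"
  }
  slen <- if (config$scope_extent == "full") Inf else
    1L + stats::rpois(1, 2)
  if (!continuous) slen <- max(slen, 2L)
  ends_at_edge <- config$scope_extent == "full" ||
    stats::runif(1) < 0.3  # some scopes run to the sentence edge
  if (morph) {
    p <- sample.int(m + 1L, 1L)            # insert anywhere
    toks <- append(seg, cue_toks, after = p - 1L)
    cue_rng <- c(p, p + length(cue_toks) - 1L)
    scope_frags <- list()
  } else if (dir == "right" || dir == "gap_right") {
    p <- sample.int(m, 1L)                 # cue before filler position p
    toks <- append(seg, cue_toks, after = p - 1L)
    first <- p + length(cue_toks)
    avail <- length(toks) - first + 1L
    len <- if (ends_at_edge) avail else min(slen, avail)
    cue_rng <- c(p, p + length(cue_toks) - 1L)
    if (dir == "gap_right" && len >= 3L) {
      a <- max(1L, len %/% 2L)
      scope_frags <- list(c(first, first + a - 1L),
                          c(first + a + 1L, first + len - 1L))
    } else {
      scope_frags <- list(c(first, first + len - 1L))
    }
  } else if (dir == "left" || dir == "gap_left") {
    p <- sample.int(m, 1L)                 # cue after filler position p
    toks <- append(seg, cue_toks, after = p)
    len <- min(if (is.finite(slen)) slen else p, p)
    cue_rng <- c(p + 1L, p + length(cue_toks))
    lo <- p - len + 1L
    if (dir == "gap_left" && len >= 3L) {
      a <- max(1L, len %/% 2L)
      scope_frags <- list(c(lo, lo + a - 1L), c(lo + a + 1L, p))
    } else {
      scope_frags <- list(c(lo, p))
    }
  } else {  # both sides of the cue: two fragments around it
    p <- sample.int(max(1L, m - 1L), 1L) + 1L  # cue between p-1 and p
    toks <- append(seg, cue_toks, after = p - 1L)
    ll <- min(1L + stats::rpois(1, 1), p - 1L)
    first <- p + length(cue_toks)
    avail <- length(toks) - first + 1L
    rl <- min(1L + stats::rpois(1, 1), avail)
    cue_rng <- c(p, p + length(cue_toks) - 1L)
    scope_frags <- list(c(p - ll, p - 1L), c(first, first + rl - 1L))
    scope_frags <- Filter(function(r) r[2] >= r[1], scope_frags)
  }
  cue_id <- paste0("T", ann_counter + 1L)
  anns[[1]] <- list(type = "cue", id = cue_id, kind = kind,
                    cue_class = row$class,
                    rng = list(cue_rng + offset))
  if (length(scope_frags) > 0L) {
    anns[[2]] <- list(type = "scope", id = paste0("T", ann_counter + 2L),
                      kind = kind, cue_id = cue_id,
                      rng = lapply(scope_frags, function(r) r + offset))
  }
  list(tokens = toks, anns = anns)
}

# Join tokens (punctuation attaches to the previous token), compute
# character offsets, and materialize annotation records.
assemble_sentence <- function(tokens, anns, doc_id) {
  is_punct <- !grepl("[\\p{L}\\p{N}]", tokens, perl = TRUE)
  sep <- c("", ifelse(is_punct[-1L], "", " "))
  starts <- integer(length(tokens)); pos <- 0L
  for (i in seq_along(tokens)) {
    pos <- pos + nchar(sep[i])
    starts[i] <- pos
    pos <- pos + nchar(tokens[i])
  }
  text <- paste0(paste0(sep, tokens), collapse = "")
  tok_df <- data.frame(text = tokens, char_start = starts,
                       char_end = starts + nchar(tokens),
                       stringsAsFactors = FALSE)
  rng_to_frag <- function(rng) data.frame(
    char_start = tok_df$char_start[vapply(rng, `[`, 0, 1L)],
    char_end = tok_df$char_end[vapply(rng, `[`, 0, 2L)])
  cues <- list(); scopes <- list()
  for (a in anns) {
    frag <- rng_to_frag(a$rng)
    if (a$type == "cue") {
      cues[[length(cues) + 1L]] <- cue_annotation(
        a$id, a$kind, a$cue_class, frag, fragment_surface(text, frag))
    } else {
      scopes[[length(scopes) + 1L]] <- scope_annotation(
        a$id, a$kind, frag, a$cue_id)
    }
  }
  annotated_sentence(text, doc_id, cues = cues, scopes = scopes,
                     tokens = tok_df)
}
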