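# Evaluation protocol: token-level (partial match) precision/recall/F1,
# entity-level exact match, support-weighted label rollups, inter-annotator
# agreement as F-measure, and k-fold cross-validation.

metric <- function(correct, predicted, gold) {
  p_def <- predicted > 0; r_def <- gold > 0
  p <- if (p_def) correct / predicted else 0
  r <- if (r_def) correct / gold else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(precision = p, recall = r, f1 = f1, support = gold,
                 defined = p_def && r_def,
                 correct = correct, predicted = predicted),
            class = "nsc_metric")
}

#' @export
print.nsc_metric <- function(x, ...) {
  cat(sprintf("P %.2f  R %.2f  F1 %.2f  (support %d%s)\n", x$precision,
              x$recall, x$f1, x$support,
              if (x$defined) "" else ", undefined"))
  invisible(x)
}

#' Token-level precision/recall/F1 over a label subset
#'
#' Partial match: every token is scored independently. A token counts as
#' predicted if its predicted label is in `labels`, as gold if its gold
#' label is, and as correct if both hold and the labels are equal.
#' Precision is correct/predicted, recall correct/gold, F1 their harmonic
#' mean; a zero denominator yields 0 with `defined = FALSE`.
#'
#' @param gold,pred Lists of aligned per-sentence label vectors (PAD
#'   already stripped).
#' @param labels Label subset under evaluation (default: everything except
#'   `O` and `PAD`).
#' @return An `nsc_metric`.
#' @export
token_prf <- function(gold, pred, labels = NULL) {
  if (length(gold) != length(pred))
    stop("gold has ", length(gold), " sentences, pred has ", length(pred))
  correct <- predicted <- gold_n <- 0L
  for (s in seq_along(gold)) {
    g <- gold[[s]]; p <- pred[[s]]
    if (length(g) != length(p))
      stop("length mismatch in sentence ", s, ": gold ", length(g),
           " vs pred ", length(p))
    keep <- g != "PAD" & p != "PAD"
    g <- g[keep]; p <- p[keep]
    subset <- labels %||% setdiff(unique(c(g, p)), c("O", "PAD"))
    gin <- g %in% subset; pin <- p %in% subset
    gold_n <- gold_n + sum(gin)
    predicted <- predicted + sum(pin)
    correct <- correct + sum(gin & pin & g == p)
  }
  metric(correct, predicted, gold_n)
}

#' Entity-level exact match
#'
#' A predicted entity is correct iff an unmatched gold entity of the same
#' category with the identical token-index set exists; matching is greedy
#' 1:1 in token order, so duplicate identical predictions count once.
#'
#' @param gold_entities,pred_entities Lists (one element per sentence) of
#'   [decode_entities()] outputs.
#' @param category Optional category filter (`"NEG"`, `"NSCO"`, `"UNC"`,
#'   `"USCO"`); default scores all categories jointly.
#' @return An `nsc_metric`.
#' @export
exact_match_prf <- function(gold_entities, pred_entities, category = NULL) {
  stopifnot(length(gold_entities) == length(pred_entities))
  correct <- predicted <- gold_n <- 0L
  for (s in seq_along(gold_entities)) {
    pick <- function(ents) if (is.null(category)) ents else
      Filter(function(e) e$category == category, ents)
    ge <- pick(gold_entities[[s]]); pe <- pick(pred_entities[[s]])
    gold_n <- gold_n + length(ge)
    predicted <- predicted + length(pe)
    used <- rep(FALSE, length(ge))
    for (e in pe) {
      for (k in seq_along(ge)) {
        if (!used[k] && ge[[k]]$category == e$category &&
            identical(sort(ge[[k]]$token_indices),
                      sort(e$token_indices))) {
          used[k] <- TRUE
          correct <- correct + 1L
          break
        }
      }
    }
  }
  metric(correct, predicted, gold_n)
}

#' Support-weighted rollup of per-label metrics
#'
#' Each of precision, recall and F1 is the support-weighted mean of the
#' constituent labels' values (not recomputed from pooled counts); the
#' rollup support is the sum. This is the reduction that produces the
#' cue/scope task scores from the per-BIO-label table.
#'
#' @param label_metrics Named list of `nsc_metric` (or a per-label table
#'   data.frame with columns `label`, `precision`, `recall`, `f1`,
#'   `support`).
#' @param group Labels to roll up, e.g. `c("B-NEG", "I-NEG")`.
#' @return An `nsc_metric` (with `defined = FALSE` on zero total support).
#' @export
weighted_rollup <- function(label_metrics, group) {
  if (is.data.frame(label_metrics)) {
    rows <- label_metrics[match(group, label_metrics$label), ]
    if (anyNA(rows$label)) stop("missing labels: ",
                                paste(setdiff(group, label_metrics$label),
                                      collapse = ", "))
    p <- rows$precision; r <- rows$recall; f <- rows$f1; w <- rows$support
  } else {
    ms <- label_metrics[group]
    if (any(vapply(ms, is.null, NA)))
      stop("missing labels: ",
           paste(group[vapply(ms, is.null, NA)], collapse = ", "))
    p <- vapply(ms, `[[`, 0, "precision")
    r <- vapply(ms, `[[`, 0, "recall")
    f <- vapply(ms, `[[`, 0, "f1")
    w <- vapply(ms, `[[`, 0, "support")
  }
  tot <- sum(w)
  if (tot == 0) {
    out <- metric(0L, 0L, 0L)
  } else {
    out <- structure(list(precision = sum(p * w) / tot,
                          recall = sum(r * w) / tot,
                          f1 = sum(f * w) / tot,
                          support = tot, defined = TRUE,
                          correct = NA_real_, predicted = NA_real_),
                     class = "nsc_metric")
  }
  out
}

categories <- function(alphabet) {
  intersect(c("NEG", "NSCO", "UNC", "USCO"),
            unique(sub("^[BI]-", "",
                       grep("^[BI]-", alphabet$labels, value = TRUE))))
}

#' Full evaluation report: per-label metrics plus task rollups
#'
#' Per-label token metrics over the whole alphabet, and per task
#' (negation/uncertainty x cue/scope) both the partial-match rollup
#' (support-weighted mean of the B- and I- label metrics) and the
#' entity-level exact match over decoded entities.
#'
#' @param gold,pred Lists of aligned label vectors.
#' @param alphabet The label alphabet in use.
#' @return An `nsc_label_report`: `per_label` data.frame and `rollups`
#'   (nested list `[[category]][[match]]` of `nsc_metric`).
#' @export
label_report <- function(gold, pred, alphabet = label_alphabet()) {
  labs <- setdiff(alphabet$labels, "PAD")
  per <- lapply(labs, function(l) token_prf(gold, pred, l))
  names(per) <- labs
  per_df <- data.frame(
    label = labs,
    precision = vapply(per, `[[`, 0, "precision"),
    recall = vapply(per, `[[`, 0, "recall"),
    f1 = vapply(per, `[[`, 0, "f1"),
    support = vapply(per, `[[`, 0, "support"),
    row.names = NULL)
  ge <- lapply(gold, decode_entities)
  pe <- lapply(pred, decode_entities)
  rollups <- lapply(categories(alphabet), function(cat_) {
    list(partial = weighted_rollup(per, paste0(c("B-", "I-"), cat_)),
         exact = exact_match_prf(ge, pe, category = cat_))
  })
  names(rollups) <- categories(alphabet)
  structure(list(per_label = per_df, rollups = rollups),
            class = "nsc_label_report")
}

#' @export
print.nsc_label_report <- function(x, digits = 2, ...) {
  cat("Per-label results\n")
  df <- x$per_label
  df$precision <- round_half_even(df$precision, digits)
  df$recall <- round_half_even(df$recall, digits)
  df$f1 <- round_half_even(df$f1, digits)
  print(df, row.names = FALSE)
  cat("\nTask rollups (partial | exact F1)\n")
  task_name <- c(NEG = "Negation cue", NSCO = "Negation scope",
                 UNC = "Uncertainty cue", USCO = "Uncertainty scope")
  for (cat_ in names(x$rollups)) {
    cat(sprintf("  %-18s %.2f | %.2f\n", task_name[[cat_]],
                x$rollups[[cat_]]$partial$f1, x$rollups[[cat_]]$exact$f1))
  }
  invisible(x)
}

#' Serialize a label report to JSON (raw, unrounded values)
#' @param report An `nsc_label_report`.
#' @param path Output file.
#' @export
write_label_report <- function(report, path) {
  jsonlite::write_json(
    list(per_label = report$per_label,
         rollups = lapply(report$rollups, function(r)
           lapply(r, unclass))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Inter-annotator agreement as F-measure
#'
#' One annotator (A) is taken as the reference; precision is the fraction
#' of B's annotations that agree with A, recall the fraction of A's
#' annotations B reproduced. At token level each annotated token is scored
#' independently; at entity level a cue/scope counts only when both
#' annotators annotated the identical token set.
#'
#' @param corpus_a,corpus_b The same sentences with each annotator's
#'   annotations (annotator A is the reference).
#' @param level `"token"` or `"entity"`.
#' @return An `nsc_iaa_report` data.frame: category, level, precision,
#'   recall, f1.
#' @export
iaa <- function(corpus_a, corpus_b, level = c("token", "entity")) {
  level <- match.arg(level)
  if (length(corpus_a) != length(corpus_b) ||
      !all(vapply(seq_along(corpus_a), function(i)
        identical(corpus_a[[i]]$text, corpus_b[[i]]$text), NA)))
    stop("annotator corpora must cover the same sentences")
  alphabet <- label_alphabet()
  ga <- lapply(corpus_a, to_bio, alphabet = alphabet)
  gb <- lapply(corpus_b, to_bio, alphabet = alphabet)
  cats <- c(NEG = "Negation cue", NSCO = "Negation scope",
            UNC = "Uncertainty cue", USCO = "Uncertainty scope")
  rows <- lapply(names(cats), function(cat_) {
    m <- if (level == "token") {
      token_prf(ga, gb, paste0(c("B-", "I-"), cat_))
    } else {
      exact_match_prf(lapply(ga, decode_entities),
                      lapply(gb, decode_entities), category = cat_)
    }
    data.frame(category = cats[[cat_]], level = level,
               precision = m$precision, recall = m$recall, f1 = m$f1,
               support = m$support, defined = m$defined, row.names = NULL)
  })
  structure(do.call(rbind, rows), class = c("nsc_iaa_report", "data.frame"))
}

#' k-fold cross-validation of a tagger
#'
#' Sentences are shuffled by `seed` and partitioned into `k` near-equal
#' disjoint folds; for each fold the model factory is trained on the other
#' k-1 folds and evaluated on the held-out fold. The averaged report is the
#' unweighted mean of the per-fold metrics.
#'
#' @param corpus Annotated corpus.
#' @param k Number of folds (`k <=` number of sentences).
#' @param model_factory `function(train_corpus)` returning a fitted model
#'   whose `predict` method yields label sequences.
#' @param seed Shuffle seed.
#' @param alphabet Label alphabet (defaults to the corpus's).
#' @return List with `average` (mean per-label/rollup values), `folds`
#'   (per-fold `nsc_label_report`s) and `assignments`.
#' @export
cross_validate <- function(corpus, k, model_factory, seed = 13L,
                           alphabet = NULL) {
  n <- length(corpus)
  if (k > n) stop("k = ", k, " exceeds corpus size ", n)
  alphabet <- alphabet %||% build_dictionaries(corpus)$alphabet
  assignment <- with_local_seed(seed, {
    idx <- sample.int(n)
    folds <- rep_len(seq_len(k), n)
    stats::setNames(folds[order(idx)], NULL)
  })
  reports <- vector("list", k)
  for (fold in seq_len(k)) {
    test_idx <- which(assignment == fold)
    train <- corpus[-test_idx]
    test <- corpus[test_idx]
    model <- model_factory(structure(train, class = "nsc_corpus"))
    gold <- lapply(test, to_bio, alphabet = alphabet)
    pred <- predict(model, test)
    reports[[fold]] <- label_report(gold, pred, alphabet)
  }
  avg <- reports[[1L]]
  per <- avg$per_label
  for (col in c("precision", "recall", "f1", "support")) {
    per[[col]] <- rowMeans(sapply(reports, function(r) r$per_label[[col]]))
  }
  avg$per_label <- per
  for (cat_ in names(avg$rollups)) {
    for (m in c("partial", "exact")) {
      for (fld in c("precision", "recall", "f1", "support")) {
        avg$rollups[[cat_]][[m]][[fld]] <-
          mean(vapply(reports, function(r)
            r$rollups[[cat_]][[m]][[fld]], 0))
      }
    }
  }
  list(average = avg, folds = reports, assignments = assignment)
}
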