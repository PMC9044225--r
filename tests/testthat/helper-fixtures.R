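# Shared fixtures: all built in code at test time.

# Published per-BIO-label results table (precision, recall, F1, support)
# for the recurrent tagger with biomedical embeddings on the large public
# corpus; used as input data for rollup checks.
published_label_rows <- function() {
  data.frame(
    label = c("B-NEG", "B-NSCO", "B-UNC", "B-USCO", "I-NEG", "I-NSCO",
              "I-UNC", "I-USCO", "O"),
    precision = c(0.95, 0.93, 0.86, 0.84, 0.89, 0.92, 0.85, 0.82, 0.98),
    recall = c(0.93, 0.91, 0.84, 0.79, 0.86, 0.88, 0.75, 0.77, 0.99),
    f1 = c(0.94, 0.92, 0.85, 0.81, 0.87, 0.90, 0.80, 0.79, 0.98),
    support = c(1423L, 1322L, 400L, 400L, 120L, 3901L, 168L, 1513L, 41977L))
}

# one-cue one-scope sentence built by hand (offsets computed from the text)
simple_neg_sentence <- function() {
  annotated_sentence(
    "La biopsia no muestra células cancerígenas",
    cues = list(cue_annotation("T1", "negation", "syntactic",
                               data.frame(char_start = 11, char_end = 13),
                               "no")),
    scopes = list(scope_annotation("T2", "negation",
                                   data.frame(char_start = 14,
                                              char_end = 42), "T1")))
}

# entity key for fragment-level round-trip comparison
entity_keys <- function(entities) {
  sort(vapply(entities, function(e)
    paste(e$kind, e$role, paste(e$token_indices, collapse = ",")), ""))
}

# gold fragment keys of a sentence (each annotation fragment separately)
gold_fragment_keys <- function(s) {
  keys <- character(0)
  for (a in c(s$cues, s$scopes)) {
    role <- if (inherits(a, "nsc_cue")) "cue" else "scope"
    for (i in seq_len(nrow(a$fragments))) {
      idx <- which(s$tokens$char_start < a$fragments$char_end[i] &
                     s$tokens$char_end > a$fragments$char_start[i])
      keys <- c(keys, paste(a$kind, role, paste(idx, collapse = ",")))
    }
  }
  sort(keys)
}

# mock tagger whose predictions are a fixed function of the tokens;
# used to exercise cross-validation mechanics without training
make_rule_tagger <- function(alphabet) {
  model <- structure(list(alphabet = alphabet), class = "nsc_rule_tagger")
  model
}
predict.nsc_rule_tagger <- function(object, sentences, ...) {
  lapply(sentences, function(s) {
    toks <- if (is.character(s)) s else s$tokens$text
    ifelse(toks %in% c("no", "sin", "niega", "negativo"), "B-NEG", "O")
  })
}
registerS3method("predict", "nsc_rule_tagger", predict.nsc_rule_tagger)
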