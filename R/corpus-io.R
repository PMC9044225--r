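# Corpus ingestion: BRAT standoff parsing, tokenization, sentence
# segmentation, and descriptive corpus statistics.

#' Tokenize a sentence
#'
#' Deterministic rule-based tokenizer: maximal runs of letters/digits
#' (including accented characters) form one token; every other
#' non-whitespace character is a single-character token. Character offsets
#' are 0-based half-open and recover the exact substrings of the input.
#'
#' @param text A sentence as a single string.
#' @return A data.frame with columns `text`, `char_start`, `char_end`
#'   (0-based, half-open), one row per token, in order of appearance.
#' @examples
#' tokenize("Sin dolor abdominal agudo.")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(text = character(), char_start = integer(),
                      char_end = integer(), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(
    text = substring(text, starts, starts + lens - 1L),
    char_start = starts - 1L,
    char_end = starts + lens - 1L,
    stringsAsFactors = FALSE
  )
}

#' Construct a cue annotation
#'
#' @param id Annotation identifier (e.g. `"T1"`).
#' @param kind `"negation"` or `"uncertainty"`.
#' @param cue_class One of `"syntactic"`, `"lexical"`, `"morphological"`,
#'   `"unknown"`.
#' @param fragments data.frame with `char_start`, `char_end` (0-based
#'   half-open), ordered and non-overlapping; multiple rows encode a
#'   discontinuous cue.
#' @param surface The annotated text, fragments joined by single spaces.
#' @export
cue_annotation <- function(id, kind, cue_class = "unknown", fragments, surface) {
  kind <- match.arg(kind, c("negation", "uncertainty"))
  cue_class <- match.arg(cue_class,
                         c("syntactic", "lexical", "morphological", "unknown"))
  fragments <- validate_fragments(fragments, id)
  structure(list(id = id, kind = kind, cue_class = cue_class,
                 fragments = fragments, surface = surface),
            class = "nsc_cue")
}

#' Construct a scope annotation
#'
#' @inheritParams cue_annotation
#' @param cue_id Identifier of the cue this scope belongs to.
#' @export
scope_annotation <- function(id, kind, fragments, cue_id) {
  kind <- match.arg(kind, c("negation", "uncertainty"))
  fragments <- validate_fragments(fragments, id)
  structure(list(id = id, kind = kind, fragments = fragments,
                 cue_id = cue_id, continuous = nrow(fragments) == 1L),
            class = "nsc_scope")
}

validate_fragments <- function(fragments, id = "?") {
  stopifnot(is.data.frame(fragments),
            all(c("char_start", "char_end") %in% names(fragments)))
  if (nrow(fragments) == 0L)
    stop("annotation ", id, ": fragments must be non-empty")
  fragments <- fragments[order(fragments$char_start), , drop = FALSE]
  if (any(fragments$char_start >= fragments$char_end))
    stop("annotation ", id, ": fragment with char_start >= char_end")
  if (nrow(fragments) > 1L &&
      any(fragments$char_start[-1L] < fragments$char_end[-nrow(fragments)]))
    stop("annotation ", id, ": overlapping fragments")
  rownames(fragments) <- NULL
  fragments[, c("char_start", "char_end"), drop = FALSE]
}

# Extract the annotated surface of a set of fragments from `text`
# (0-based offsets), discontinuous pieces joined by a single space.
fragment_surface <- function(text, fragments) {
  paste(substring(text, fragments$char_start + 1L, fragments$char_end),
        collapse = " ")
}

#' Construct an annotated sentence
#'
#' The unit of all tagging and evaluation: a tokenized sentence plus its
#' linked cue and scope annotations with sentence-local character offsets.
#' Validity is enforced on construction: annotation fragments must lie
#' within the sentence, every scope's `cue_id` must resolve to a cue of the
#' sentence, and scope fragments must not overlap their cue's fragments.
#'
#' @param text Sentence string.
#' @param doc_id Source document identifier.
#' @param cues List of [cue_annotation()] objects.
#' @param scopes List of [scope_annotation()] objects.
#' @param tokens Optional pre-computed token table; defaults to
#'   `tokenize(text)`.
#' @return An object of class `nsc_sentence`.
#' @export
annotated_sentence <- function(text, doc_id = "doc", cues = list(),
                               scopes = list(), tokens = NULL) {
  tokens <- tokens %||% tokenize(text)
  nch <- nchar(text)
  cue_ids <- vapply(cues, `[[`, "", "id")
  for (a in c(cues, scopes)) {
    if (any(a$fragments$char_start < 0L) || any(a$fragments$char_end > nch))
      stop("annotation ", a$id, " lies outside sentence [0,", nch, ")")
  }
  for (cu in cues) {
    expected <- fragment_surface(text, cu$fragments)
    if (!identical(squeeze_ws(expected), squeeze_ws(cu$surface)))
      stop("cue ", cu$id, ": surface ", dQuote(cu$surface),
           " does not match document text ", dQuote(expected))
  }
  for (sc in scopes) {
    if (!sc$cue_id %in% cue_ids)
      stop("scope ", sc$id, ": cue_id ", sc$cue_id, " not in sentence")
    cu <- cues[[match(sc$cue_id, cue_ids)]]
    if (fragments_overlap(sc$fragments, cu$fragments))
      stop("scope ", sc$id, " overlaps its cue ", cu$id)
  }
  structure(list(text = text, doc_id = doc_id, tokens = tokens,
                 cues = cues, scopes = scopes),
            class = "nsc_sentence")
}

squeeze_ws <- function(x) gsub("\\s+", " ", x, perl = TRUE)

fragments_overlap <- function(a, b) {
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      if (a$char_start[i] < b$char_end[j] && b$char_start[j] < a$char_end[i])
        return(TRUE)
  FALSE
}

#' @export
print.nsc_sentence <- function(x, ...) {
  cat(sprintf("<nsc_sentence> %s | %d tokens, %d cue(s), %d scope(s)\n",
              dQuote(x$text), nrow(x$tokens), length(x$cues), length(x$scopes)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Standoff dialects: entity-type name -> (role, kind, class). The public
# releases describe their label classes verbally, so the nubes/iula tables
# carry the documented vocabulary plus common aliases and default to lenient
# handling of unknown types; "generic" is the package's own round-trip
# dialect and is strict.

standoff_dialects <- function() {
  ent <- function(role, kind, cue_class = "unknown")
    list(role = role, kind = kind, cue_class = cue_class)
  generic <- list(
    NegCue = ent("cue", "negation"),
    UncCue = ent("cue", "uncertainty"),
    NegScope = ent("scope", "negation"),
    UncScope = ent("scope", "uncertainty")
  )
  nubes <- c(generic, list(
    Neg = ent("cue", "negation"),
    NegMarker = ent("cue", "negation"),
    NegSyn = ent("cue", "negation", "syntactic"),
    NegLex = ent("cue", "negation", "lexical"),
    NegMorph = ent("cue", "negation", "morphological"),
    Negation = ent("cue", "negation"),
    Unc = ent("cue", "uncertainty"),
    Spec = ent("cue", "uncertainty"),
    SpecMarker = ent("cue", "uncertainty"),
    Uncertainty = ent("cue", "uncertainty"),
    NSco = ent("scope", "negation"),
    NSCO = ent("scope", "negation"),
    USco = ent("scope", "uncertainty"),
    USCO = ent("scope", "uncertainty"),
    Scope = ent("scope", NA_character_)   # kind resolved from linked cue
  ))
  iula <- list(
    NegCue = ent("cue", "negation"),
    Neg = ent("cue", "negation"),
    NegMarker = ent("cue", "negation"),
    NegationCue = ent("cue", "negation"),
    NegScope = ent("scope", "negation"),
    Scope = ent("scope", "negation")
  )
  list(generic = generic, nubes = nubes, iula = iula)
}

#' Parse BRAT standoff annotation content
#'
#' Parses entity (`T`), relation (`R`) and attribute (`A`) lines of a BRAT
#' `.ann` file against its paired document text. Discontinuous entities
#' (`;`-separated span lists) yield multi-fragment records. Offsets are
#' 0-based half-open; every entity surface is validated against the
#' document text.
#'
#' @param ann_content The `.ann` file content as a single string (or vector
#'   of lines).
#' @param doc_content The exact document text the offsets index into.
#' @param dialect `"generic"`, `"nubes"` or `"iula"`: entity-type mapping
#'   table.
#' @param on_unknown `"strict"` errors on unknown entity types;
#'   `"lenient"` flags them `kind = "unknown"` and excludes them downstream.
#' @return List with elements `cues` and `scopes` (document-level
#'   coordinates), each a list of annotation records.
#' @export
parse_standoff <- function(ann_content, doc_content,
                           dialect = c("generic", "nubes", "iula"),
                           on_unknown = NULL) {
  dialect <- match.arg(dialect)
  on_unknown <- on_unknown %||% if (dialect == "generic") "strict" else "lenient"
  on_unknown <- match.arg(on_unknown, c("strict", "lenient"))
  table <- standoff_dialects()[[dialect]]
  lines <- unlist(strsplit(paste(ann_content, collapse = "\n"), "\n",
                           fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  ents <- list(); rels <- list(); attrs <- list()
  for (ln in lines) {
    first <- substr(ln, 1L, 1L)
    if (first == "T") {
      m <- regmatches(ln, regexec(
        "^(T[0-9]+)\t(\\S+) ([0-9]+ [0-9]+(?:;[0-9]+ [0-9]+)*)\t(.*)$",
        ln, perl = TRUE))[[1]]
      if (length(m) == 0L) stop("malformed entity line: ", dQuote(ln))
      spans <- strsplit(m[4], ";", fixed = TRUE)[[1]]
      nums <- lapply(strsplit(spans, " ", fixed = TRUE), as.integer)
      frag <- data.frame(char_start = vapply(nums, `[`, 0L, 1L),
                         char_end = vapply(nums, `[`, 0L, 2L))
      if (any(frag$char_end > nchar(doc_content)) || any(frag$char_start < 0L))
        stop("offset outside document in line: ", dQuote(ln))
      frag <- validate_fragments(frag, m[2])
      expected <- fragment_surface(doc_content, frag)
      if (!identical(squeeze_ws(expected), squeeze_ws(m[5])))
        stop("surface mismatch in line ", dQuote(ln), ": document has ",
             dQuote(expected))
      ents[[m[2]]] <- list(id = m[2], type = m[3], fragments = frag,
                           surface = m[5])
    } else if (first == "R") {
      m <- regmatches(ln, regexec(
        "^(R[0-9]+)\t(\\S+) Arg1:(\\S+) Arg2:(\\S+)", ln, perl = TRUE))[[1]]
      if (length(m) == 0L) stop("malformed relation line: ", dQuote(ln))
      rels[[m[2]]] <- list(arg1 = m[4], arg2 = m[5])
    } else if (first == "A") {
      m <- regmatches(ln, regexec(
        "^(A[0-9]+)\t(\\S+) (T[0-9]+) ?(\\S*)", ln, perl = TRUE))[[1]]
      if (length(m) > 0L && nzchar(m[5])) attrs[[m[4]]] <- tolower(m[5])
    } else if (first == "#") {
      next  # annotator note
    } else {
      nsc_log("ignoring unsupported standoff line: ", ln, level = "debug")
    }
  }
  cues <- list(); scopes <- list()
  for (e in ents) {
    info <- table[[e$type]]
    if (is.null(info)) {
      if (on_unknown == "strict")
        stop("unknown entity type ", dQuote(e$type), " in dialect ",
             dQuote(dialect))
      nsc_log("unknown entity type ", e$type, " excluded", level = "debug")
      next
    }
    if (info$role == "cue") {
      cls <- attrs[[e$id]] %||% info$cue_class
      if (!cls %in% c("syntactic", "lexical", "morphological")) cls <- "unknown"
      cues[[e$id]] <- list(id = e$id, kind = info$kind, cue_class = cls,
                           fragments = e$fragments, surface = e$surface)
    } else {
      scopes[[e$id]] <- list(id = e$id, kind = info$kind,
                             fragments = e$fragments, surface = e$surface,
                             cue_id = NA_character_)
    }
  }
  for (r in unname(rels)) {
    a1 <- r$arg1; a2 <- r$arg2
    if (!is.null(scopes[[a2]]) && !is.null(cues[[a1]])) {
      scopes[[a2]]$cue_id <- a1
    } else if (!is.null(scopes[[a1]]) && !is.null(cues[[a2]])) {
      scopes[[a1]]$cue_id <- a2
    }
  }
  # Resolve kind of dialect-ambiguous scopes from their linked cue.
  for (sid in names(scopes)) {
    sc <- scopes[[sid]]
    if (is.na(sc$kind) && !is.na(sc$cue_id))
      scopes[[sid]]$kind <- cues[[sc$cue_id]]$kind
  }
  scopes <- Filter(function(s) !is.na(s$kind), scopes)
  list(cues = unname(cues), scopes = unname(scopes))
}

# ---------------------------------------------------------------------------
# Sentence segmentation. Rule: a run of .!? followed by whitespace and an
# uppercase letter or digit ends a sentence, unless the preceding word is a
# known abbreviation; newlines always break (clinical notes are line
# oriented).

nsc_abbreviations <- c("dr", "dra", "sr", "sra", "etc", "vs", "fig", "pag",
                       "art", "dl", "mg", "ml", "cm", "mm", "aprox")

segment_sentences <- function(text) {
  n <- nchar(text)
  if (n == 0L) return(data.frame(start = integer(), end = integer()))
  bounds <- integer()  # 0-based positions where a new sentence may begin
  m <- gregexpr("[.!?]+(?=[ \t]+[\\p{Lu}0-9])", text, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    for (i in seq_along(m)) {
      term_end <- as.integer(m[i]) + attr(m, "match.length")[i] - 1L
      before <- substr(text, max(1L, as.integer(m[i]) - 12L), as.integer(m[i]) - 1L)
      word <- sub("^.*?([\\p{L}]+)$", "\\1", before, perl = TRUE)
      if (tolower(word) %in% nsc_abbreviations && !grepl("[\\p{L}]\\s", before, perl = TRUE))
        next
      bounds <- c(bounds, term_end)  # sentence ends after the terminator
    }
  }
  nl <- gregexpr("\n", text, fixed = TRUE)[[1]]
  if (nl[1] != -1L) bounds <- c(bounds, as.integer(nl) - 1L)
  bounds <- sort(unique(c(bounds, n)))
  spans <- data.frame(start = integer(), end = integer())
  prev <- 0L
  for (b in bounds) {
    s <- prev; e <- b
    # trim whitespace
    while (s < e && grepl("^\\s", substr(text, s + 1L, s + 1L))) s <- s + 1L
    while (e > s && grepl("^\\s", substr(text, e, e))) e <- e - 1L
    if (e > s) spans <- rbind(spans, data.frame(start = s, end = e))
    prev <- b
  }
  spans
}

#' Load a standoff-annotated corpus from a directory
#'
#' Reads every `.txt` document (with its paired `.ann` file when present),
#' segments documents into sentences, assigns each annotation to the
#' sentence containing its first fragment, and re-bases offsets to
#' sentence-local coordinates. When an annotation (or a cue/scope pair)
#' crosses a sentence boundary, the sentences involved are merged with a
#' warning so gold spans are never truncated.
#'
#' @param path Directory containing paired `.txt`/`.ann` files.
#' @inheritParams parse_standoff
#' @return A list of [annotated_sentence()] objects with class
#'   `nsc_corpus`.
#' @export
load_corpus <- function(path, dialect = c("generic", "nubes", "iula"),
                        on_unknown = NULL) {
  dialect <- match.arg(dialect)
  txts <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
  if (length(txts) == 0L) stop("no .txt documents found under ", path)
  out <- list()
  for (txt in txts) {
    doc_id <- sub("\\.txt$", "", basename(txt))
    doc <- paste(readLines(txt, encoding = "UTF-8", warn = FALSE),
                 collapse = "\n")
    annf <- sub("\\.txt$", ".ann", txt)
    recs <- if (file.exists(annf)) {
      parse_standoff(readLines(annf, encoding = "UTF-8", warn = FALSE),
                     doc, dialect = dialect, on_unknown = on_unknown)
    } else list(cues = list(), scopes = list())
    out <- c(out, split_document(doc, doc_id, recs))
  }
  structure(out, class = "nsc_corpus")
}

split_document <- function(doc, doc_id, recs) {
  spans <- segment_sentences(doc)
  if (nrow(spans) == 0L) return(list())
  all_ann <- c(recs$cues, recs$scopes)
  sent_of <- function(pos) findInterval(pos, spans$start)  # 0-based pos
  # merge sentences until every annotation fits into a single sentence
  repeat {
    merged <- FALSE
    for (a in all_ann) {
      s1 <- sent_of(a$fragments$char_start[1L])
      s2 <- sent_of(max(a$fragments$char_end) - 1L)
      if (s1 < 1L || s2 < 1L) next
      if (s1 != s2 || max(a$fragments$char_end) > spans$end[s1]) {
        s2 <- max(s2, s1)
        warning("annotation ", a$id, " crosses a sentence boundary in ",
                doc_id, "; merging sentences", call. = FALSE)
        spans <- merge_spans(spans, s1, s2)
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  # keep cue and its scope in the same sentence
  cue_sent <- vapply(recs$cues,
                     function(cu) sent_of(cu$fragments$char_start[1L]), 0L)
  names(cue_sent) <- vapply(recs$cues, `[[`, "", "id")
  repeat {
    merged <- FALSE
    for (sc in recs$scopes) {
      if (is.na(sc$cue_id) || !sc$cue_id %in% names(cue_sent)) next
      ss <- sent_of(sc$fragments$char_start[1L])
      cs <- sent_of(recs$cues[[match(sc$cue_id,
                                     names(cue_sent))]]$fragments$char_start[1L])
      if (ss != cs) {
        warning("scope ", sc$id, " and cue ", sc$cue_id,
                " lie in different sentences in ", doc_id, "; merging",
                call. = FALSE)
        spans <- merge_spans(spans, min(ss, cs), max(ss, cs))
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  sentences <- vector("list", nrow(spans))
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]
    stext <- substring(doc, s + 1L, e)
    rebased <- function(records) {
      keep <- Filter(function(a) {
        p <- a$fragments$char_start[1L]
        p >= s && p < e
      }, records)
      lapply(keep, function(a) {
        a$fragments$char_start <- a$fragments$char_start - s
        a$fragments$char_end <- a$fragments$char_end - s
        a
      })
    }
    cs <- lapply(rebased(recs$cues), function(a)
      cue_annotation(a$id, a$kind, a$cue_class, a$fragments, a$surface))
    scs <- rebased(recs$scopes)
    scs <- Filter(function(a) !is.na(a$cue_id), scs)
    scs <- lapply(scs, function(a)
      scope_annotation(a$id, a$kind, a$fragments, a$cue_id))
    sentences[[i]] <- annotated_sentence(stext, doc_id, cues = cs, scopes = scs)
  }
  sentences
}

merge_spans <- function(spans, i, j) {
  spans$end[i] <- spans$end[j]
  if (j > i) spans <- spans[-seq(i + 1L, j), , drop = FALSE]
  rownames(spans) <- NULL
  spans
}

#' Write a corpus as BRAT standoff pairs
#'
#' One `.txt`/`.ann` pair per `doc_id`; sentence texts are joined with
#' newlines and annotation offsets re-based to document coordinates.
#' Round-trip capable with `load_corpus(dialect = "generic")`, including
#' discontinuous fragments.
#'
#' @param corpus List of annotated sentences.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the output directory.
#' @export
write_standoff <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  by_doc <- split(corpus, vapply(corpus, `[[`, "", "doc_id"))
  for (doc_id in names(by_doc)) {
    sents <- by_doc[[doc_id]]
    texts <- vapply(sents, `[[`, "", "text")
    offsets <- cumsum(c(0L, nchar(texts) + 1L))[seq_along(texts)]
    tlines <- character(); rlines <- character(); alines <- character()
    tn <- 0L; rn <- 0L; an <- 0L
    for (i in seq_along(sents)) {
      s <- sents[[i]]; off <- offsets[i]
      idmap <- character()
      for (cu in s$cues) {
        tn <- tn + 1L
        idmap[[cu$id]] <- paste0("T", tn)
        frag <- sprintf("%d %d", cu$fragments$char_start + off,
                        cu$fragments$char_end + off)
        type <- if (cu$kind == "negation") "NegCue" else "UncCue"
        tlines <- c(tlines, sprintf("T%d\t%s %s\t%s", tn, type,
                                    paste(frag, collapse = ";"), cu$surface))
        if (cu$cue_class != "unknown") {
          an <- an + 1L
          alines <- c(alines, sprintf("A%d\tCueClass T%d %s", an, tn,
                                      cu$cue_class))
        }
      }
      for (sc in s$scopes) {
        tn <- tn + 1L
        frag <- sprintf("%d %d", sc$fragments$char_start + off,
                        sc$fragments$char_end + off)
        type <- if (sc$kind == "negation") "NegScope" else "UncScope"
        tlines <- c(tlines, sprintf("T%d\t%s %s\t%s", tn, type,
                                    paste(frag, collapse = ";"),
                                    fragment_surface(s$text, sc$fragments)))
        rn <- rn + 1L
        rlines <- c(rlines, sprintf("R%d\tScope Arg1:%s Arg2:T%d", rn,
                                    idmap[[sc$cue_id]], tn))
      }
    }
    writeLines(paste(texts, collapse = "\n"),
               file.path(dir, paste0(doc_id, ".txt")), useBytes = FALSE)
    writeLines(c(tlines, alines, rlines),
               file.path(dir, paste0(doc_id, ".ann")), useBytes = FALSE)
  }
  invisible(dir)
}

# ---------------------------------------------------------------------------
# Descriptive statistics

#' Descriptive statistics of an annotated corpus
#'
#' Computes the corpus summary used throughout reporting: sentence counts,
#' the fraction of negated/uncertain sentences, token-count quantiles
#' (linear interpolation), cue totals, distinct cue surfaces (lowercased),
#' cue-class mix per kind, continuous vs discontinuous scope percentages,
#' and the fraction of scopes ending at the sentence-final (non-punctuation)
#' token. All token-level figures are relative to the package tokenizer.
#'
#' @param corpus List of annotated sentences (non-empty).
#' @return An object of class `nsc_corpus_stats`.
#' @seealso [top_k_cue_coverage()]
#' @export
corpus_statistics <- function(corpus) {
  if (length(corpus) == 0L) stop("corpus is empty")
  n <- length(corpus)
  kinds <- c("negation", "uncertainty")
  has_kind <- function(s, k) any(vapply(s$cues, function(c) c$kind == k, NA))
  negated <- vapply(corpus, has_kind, NA, "negation")
  uncertain <- vapply(corpus, has_kind, NA, "uncertainty")
  tok_counts <- vapply(corpus, function(s) nrow(s$tokens), 0L)
  cue_tab <- do.call(rbind, lapply(corpus, function(s) {
    if (length(s$cues) == 0L) return(NULL)
    data.frame(kind = vapply(s$cues, `[[`, "", "kind"),
               cue_class = vapply(s$cues, `[[`, "", "cue_class"),
               surface = tolower(vapply(s$cues, `[[`, "", "surface")),
               stringsAsFactors = FALSE)
  }))
  scope_tab <- do.call(rbind, lapply(corpus, function(s) {
    if (length(s$scopes) == 0L) return(NULL)
    last_tok <- sentence_final_token(s)
    data.frame(kind = vapply(s$scopes, `[[`, "", "kind"),
               continuous = vapply(s$scopes, `[[`, NA, "continuous"),
               final = vapply(s$scopes, function(sc) {
                 if (is.null(last_tok)) return(FALSE)
                 k <- nrow(sc$fragments)
                 sc$fragments$char_end[k] > last_tok$char_start &&
                   sc$fragments$char_start[k] < last_tok$char_end
               }, NA),
               stringsAsFactors = FALSE)
  }))
  pct <- function(x, of) if (of == 0) NA_real_ else 100 * x / of
  cue_freq <- lapply(kinds, function(k) {
    if (is.null(cue_tab)) return(table(character()))
    sort(table(cue_tab$surface[cue_tab$kind == k]), decreasing = TRUE)
  })
  names(cue_freq) <- kinds
  classes <- c("syntactic", "lexical", "morphological", "unknown")
  pct_by_class <- sapply(kinds, function(k) {
    nk <- if (is.null(cue_tab)) 0L else sum(cue_tab$kind == k)
    vapply(classes, function(cl) {
      if (nk == 0L) return(NA_real_)
      pct(sum(cue_tab$kind == k & cue_tab$cue_class == cl), nk)
    }, 0)
  })
  n_scopes <- if (is.null(scope_tab)) 0L else nrow(scope_tab)
  structure(list(
    n_sentences = n,
    pct_negated = pct(sum(negated), n),
    pct_uncertain = pct(sum(uncertain), n),
    token_count_max = max(tok_counts),
    token_count_mean = mean(tok_counts),
    token_count_median = unname(stats::quantile(tok_counts, 0.5)),
    token_count_q1 = unname(stats::quantile(tok_counts, 0.25)),
    token_count_q3 = unname(stats::quantile(tok_counts, 0.75)),
    n_negation_cues = if (is.null(cue_tab)) 0L else
      sum(cue_tab$kind == "negation"),
    n_uncertainty_cues = if (is.null(cue_tab)) 0L else
      sum(cue_tab$kind == "uncertainty"),
    n_distinct_negation_cues = length(cue_freq$negation),
    n_distinct_uncertainty_cues = length(cue_freq$uncertainty),
    pct_continuous_scopes = if (n_scopes) pct(sum(scope_tab$continuous),
                                              n_scopes) else NA_real_,
    pct_discontinuous_scopes = if (n_scopes) pct(sum(!scope_tab$continuous),
                                                 n_scopes) else NA_real_,
    pct_cues_by_class = pct_by_class,
    pct_scope_sentence_final = vapply(kinds, function(k) {
      if (is.null(scope_tab) || !any(scope_tab$kind == k)) return(NA_real_)
      pct(sum(scope_tab$final[scope_tab$kind == k]),
          sum(scope_tab$kind == k))
    }, 0),
    cue_frequencies = cue_freq
  ), class = "nsc_corpus_stats")
}

# last token of the sentence that is not pure punctuation
sentence_final_token <- function(s) {
  if (nrow(s$tokens) == 0L) return(NULL)
  alnum <- grepl("[\\p{L}\\p{N}]", s$tokens$text, perl = TRUE)
  if (!any(alnum)) return(NULL)
  s$tokens[max(which(alnum)), ]
}

#' Coverage of the k most frequent cue surfaces
#'
#' Percentage of all cue annotations of a kind accounted for by the `k`
#' most frequent (lowercased) cue surfaces.
#'
#' @param stats An `nsc_corpus_stats` object.
#' @param kind `"negation"` or `"uncertainty"`.
#' @param k Number of top surfaces.
#' @return A percentage in `[0, 100]`.
#' @export
top_k_cue_coverage <- function(stats, kind = c("negation", "uncertainty"),
                               k = 5L) {
  kind <- match.arg(kind)
  freq <- stats$cue_frequencies[[kind]]
  if (length(freq) == 0L) return(NA_real_)
  100 * sum(utils::head(freq, k)) / sum(freq)
}

#' @export
print.nsc_corpus_stats <- function(x, ...) {
  f1 <- function(v) ifelse(is.na(v), "-", sprintf("%.1f", v))
  cat("Corpus summary\n")
  cat(sprintf("  Sentences                 %d\n", x$n_sentences))
  cat(sprintf("  Sentences with negation   %s%%\n", f1(x$pct_negated)))
  cat(sprintf("  Sentences with uncertainty %s%%\n", f1(x$pct_uncertain)))
  cat(sprintf("  Tokens max/mean/median    %d / %s / %s\n",
              x$token_count_max, f1(x$token_count_mean),
              f1(x$token_count_median)))
  cat(sprintf("  Quartiles (q1, q3)        %s, %s\n", f1(x$token_count_q1),
              f1(x$token_count_q3)))
  cat(sprintf("  Negation cues             %d (%d distinct)\n",
              x$n_negation_cues, x$n_distinct_negation_cues))
  cat(sprintf("  Uncertainty cues          %d (%d distinct)\n",
              x$n_uncertainty_cues, x$n_distinct_uncertainty_cues))
  cat(sprintf("  Continuous scopes         %s%%\n",
              f1(x$pct_continuous_scopes)))
  cat(sprintf("  Discontinuous scopes      %s%%\n",
              f1(x$pct_discontinuous_scopes)))
  invisible(x)
}

#' Serialize corpus statistics to JSON
#'
#' @param stats An `nsc_corpus_stats` object.
#' @param path Output file.
#' @export
write_corpus_stats <- function(stats, path) {
  x <- unclass(stats)
  x$cue_frequencies <- lapply(x$cue_frequencies, function(t)
    as.list(stats::setNames(as.integer(t), names(t))))
  x$pct_cues_by_class <- apply(x$pct_cues_by_class, 2, as.list)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a corpus as JSON-lines
#'
#' One JSON object per sentence: `doc_id`, `text`, `tokens`, `cues`,
#' `scopes` (offsets sentence-local, 0-based half-open).
#'
#' @param corpus List of annotated sentences.
#' @param path Output file.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in corpus) {
    obj <- list(doc_id = s$doc_id, text = s$text, tokens = s$tokens,
                cues = lapply(s$cues, unclass),
                scopes = lapply(s$scopes, unclass))
    writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                             digits = NA)), con)
  }
  invisible(path)
}

#' Read a JSON-lines corpus written by [write_corpus_jsonl()]
#' @param path Input file.
#' @return An `nsc_corpus` list of annotated sentences.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  frag_df <- function(fr) data.frame(
    char_start = vapply(fr, function(f) as.integer(f$char_start), 0L),
    char_end = vapply(fr, function(f) as.integer(f$char_end), 0L))
  out <- lapply(lines, function(ln) {
    o <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    cues <- lapply(o$cues, function(cu)
      cue_annotation(cu$id, cu$kind, cu$cue_class, frag_df(cu$fragments),
                     cu$surface))
    scopes <- lapply(o$scopes, function(sc)
      scope_annotation(sc$id, sc$kind, frag_df(sc$fragments), sc$cue_id))
    annotated_sentence(o$text, o$doc_id, cues = cues, scopes = scopes)
  })
  structure(out, class = "nsc_corpus")
}
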