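# Orchestration glue: YAML run configuration with per-architecture
# defaults, command dispatch, model checkpoints and run manifests.

#' Save / load a tagger checkpoint
#'
#' Checkpoints are plain-text directories: weights as JSON (full double
#' precision), the token dictionary / WordPiece vocabulary, the label
#' alphabet, and the training configuration.
#'
#' @param model An `nsc_bilstm_crf` or `nsc_transformer`.
#' @param dir Checkpoint directory (created).
#' @export
save_tagger <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arch <- if (inherits(model, "nsc_bilstm_crf")) "bilstm-crf" else
    if (inherits(model, "nsc_transformer")) "transformer" else
      stop("unknown model class")
  meta <- list(architecture = arch, alphabet = model$alphabet$labels,
               config = unclass(model$cfg), loss_trace = model$loss_trace)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(flatten_weights(model$weights),
                       file.path(dir, "weights.json"), digits = NA)
  if (arch == "bilstm-crf") {
    if (!is.null(model$dt)) write_token_dict(model$dt,
                                             file.path(dir, "tokens.json"))
  } else {
    jsonlite::write_json(as.list(model$tokenizer$to_id),
                         file.path(dir, "wordpiece.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  kinds <- c(if (any(grepl("NEG", meta$alphabet))) "negation",
             if (any(grepl("UNC", meta$alphabet))) "uncertainty")
  alphabet <- label_alphabet(kinds)
  stopifnot(identical(alphabet$labels, meta$alphabet))
  w <- unflatten_weights(jsonlite::fromJSON(file.path(dir, "weights.json"),
                                            simplifyMatrix = TRUE))
  if (meta$architecture == "bilstm-crf") {
    cfg <- do.call(train_config, meta$config)
    dt <- if (file.exists(file.path(dir, "tokens.json")))
      read_token_dict(file.path(dir, "tokens.json")) else NULL
    structure(list(weights = w, dt = dt, alphabet = alphabet, cfg = cfg,
                   emb_source = "checkpoint", dim = ncol(w$E),
                   loss_trace = meta$loss_trace),
              class = "nsc_bilstm_crf")
  } else {
    cfg <- do.call(finetune_config, meta$config)
    to_id <- unlist(jsonlite::fromJSON(file.path(dir, "wordpiece.json")))
    tokenizer <- structure(list(vocab = names(to_id), to_id = to_id),
                           class = "nsc_wordpiece")
    structure(list(weights = w, tokenizer = tokenizer, alphabet = alphabet,
                   cfg = cfg, loss_trace = meta$loss_trace),
              class = "nsc_transformer")
  }
}

# nested weight lists <-> flat named-matrix lists ("layers.2.Wq") so that
# checkpoints survive a JSON round trip without structural ambiguity
flatten_weights <- function(w, prefix = NULL) {
  out <- list()
  for (nm in seq_along(w)) {
    key <- if (is.null(names(w)) || !nzchar(names(w)[nm]))
      as.character(nm) else names(w)[nm]
    full <- paste(c(prefix, key), collapse = ".")
    x <- w[[nm]]
    if (is.list(x)) out <- c(out, flatten_weights(x, full))
    else out[[full]] <- x
  }
  out
}

unflatten_weights <- function(flat) {
  out <- list()
  for (full in names(flat)) {
    path <- strsplit(full, ".", fixed = TRUE)[[1]]
    path <- lapply(path, function(p)
      if (grepl("^[0-9]+$", p)) as.integer(p) else p)
    out <- assign_path(out, path, as.matrix(flat[[full]]))
  }
  out
}

assign_path <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path[[1L]]]] <- value
    return(x)
  }
  key <- path[[1L]]
  sub <- if (is.numeric(key) && length(x) >= key) x[[key]]
  else if (!is.numeric(key)) x[[key]]
  else NULL
  x[[key]] <- assign_path(sub %||% list(), path[-1L], value)
  x
}

run_config_defaults <- function(command, architecture) {
  base <- list(seed = 13L, dialect = "generic", log_level = "info")
  arch <- switch(architecture %||% "none",
                 "bilstm-crf" = list(learning_rate = 0.001, dropout = 0.5,
                                     epochs = 60L, hidden = 300L,
                                     batch = 512L),
                 "transformer" = list(max_sequence_length = 256L,
                                      batch = 64L, epochs = 5L,
                                      learning_rate = 1e-3),
                 list())
  c(base, arch)
}

run_config_required <- function(command) {
  switch(command,
         train = c("corpus", "out"),
         predict = c("model", "input", "out"),
         evaluate = c("gold", "pred"),
         stats = "input",
         iaa = c("a", "b"),
         generate = c("n", "out"),
         character(0))
}

#' Load and validate a run configuration
#'
#' Reads a YAML key-value document, fills architecture defaults (the
#' published hyperparameters), rejects unknown keys, and checks the paths
#' the command requires.
#'
#' @param path YAML config file (may be empty).
#' @param command One of train, predict, evaluate, stats, iaa, generate.
#' @param architecture `"bilstm-crf"` or `"transformer"` (train/predict).
#' @param overrides Named list overriding file values (CLI flags).
#' @return An `nsc_run_config` list.
#' @export
load_run_config <- function(path = NULL, command, architecture = NULL,
                            overrides = list()) {
  command <- match.arg(command, c("train", "predict", "evaluate", "stats",
                                  "iaa", "generate"))
  user <- list()
  if (!is.null(path) && file.exists(path)) {
    user <- yaml::read_yaml(path) %||% list()
  }
  user <- utils::modifyList(user, overrides)
  architecture <- architecture %||% user$architecture
  defaults <- run_config_defaults(command, architecture)
  known <- unique(c(names(defaults), run_config_required(command),
                    "architecture", "embeddings", "encoder", "match",
                    "level", "out", "n", "dropout", "hidden", "batch",
                    "epochs", "learning_rate", "max_sequence_length",
                    "dim", "layers", "heads", "ffn", "min_count"))
  unknown <- setdiff(names(user), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  cfg$command <- command
  cfg$architecture <- architecture
  missing <- setdiff(run_config_required(command), names(cfg))
  if (length(missing) > 0L)
    stop("missing required key(s) for ", command, ": ",
         paste(missing, collapse = ", "))
  structure(cfg, class = "nsc_run_config")
}

write_manifest <- function(config, out_dir, inputs = character(0)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  checks <- if (length(inputs) > 0L) {
    files <- unlist(lapply(inputs, function(p)
      if (dir.exists(p)) list.files(p, full.names = TRUE) else p))
    files <- files[file.exists(files)]
    as.list(tools::md5sum(files))
  } else list()
  manifest <- list(config = unclass(config),
                   input_checksums = checks,
                   package_version = as.character(
                     utils::packageVersion("negscope")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Execute a validated run configuration
#'
#' Dispatches to the corresponding module pipeline and writes a manifest
#' (resolved config, input checksums, versions) beside the outputs, enough
#' to replay the run to identical reports.
#'
#' @param config An `nsc_run_config` from [load_run_config()].
#' @return Invisibly, a list of artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "nsc_run_config"))
  old <- options(negscope.log_level = config$log_level %||% "info")
  on.exit(options(old))
  seed <- config$seed %||% 13L
  switch(config$command,
    generate = {
      gen <- default_config_nubeslike()
      corpus <- generate_corpus(gen, n = config$n,
                                seed = derive_seed(seed, "generator"))
      write_standoff(corpus, config$out)
      write_corpus_jsonl(corpus, file.path(config$out, "corpus.jsonl"))
      write_manifest(config, config$out)
      invisible(list(out = config$out))
    },
    stats = {
      corpus <- load_corpus(config$input, dialect = config$dialect)
      st <- corpus_statistics(corpus)
      out <- config$out %||% file.path(config$input, "stats.json")
      write_corpus_stats(st, out)
      invisible(list(stats = out))
    },
    train = {
      corpus <- load_corpus(config$corpus, dialect = config$dialect)
      dicts <- build_dictionaries(corpus)
      model <- if (identical(config$architecture, "transformer")) {
        cfg <- finetune_config(
          max_sequence_length = config$max_sequence_length,
          batch = config$batch, epochs = config$epochs,
          learning_rate = config$learning_rate,
          seed = derive_seed(seed, "train"),
          dim = config$dim %||% 32L, layers = config$layers %||% 2L,
          heads = config$heads %||% 2L, ffn = config$ffn %||% 128L)
        finetune(corpus, cfg, alphabet = dicts$alphabet)
      } else {
        emb <- if (!is.null(config$embeddings))
          load_word_vectors(config$embeddings, dicts$dt,
                            seed = derive_seed(seed, "embeddings"))
        else load_word_vectors(NULL, dicts$dt, dim = config$dim %||% 300L,
                               seed = derive_seed(seed, "embeddings"))
        cfg <- train_config(learning_rate = config$learning_rate,
                            dropout = config$dropout,
                            epochs = config$epochs, hidden = config$hidden,
                            batch = config$batch,
                            seed = derive_seed(seed, "train"))
        batch <- encode_matrices(corpus, dicts$dt, dicts$alphabet)
        train_bilstm_crf(batch, emb, cfg, dt = dicts$dt)
      }
      save_tagger(model, config$out)
      write_manifest(config, config$out, inputs = config$corpus)
      invisible(list(model = config$out))
    },
    predict = {
      model <- load_tagger(config$model)
      corpus <- load_corpus(config$input, dialect = config$dialect)
      gold <- lapply(corpus, to_bio, alphabet = model$alphabet)
      pred <- predict(model, corpus)
      write_conll(corpus, gold, pred, config$out)
      write_manifest(config, dirname(config$out), inputs = config$input)
      invisible(list(predictions = config$out))
    },
    evaluate = {
      g <- read_conll(config$gold)
      pred <- if (!is.null(config$pred) && config$pred != config$gold)
        read_conll(config$pred)$gold else g$pred
      if (is.null(pred)) stop("no predictions found")
      if (length(g$gold) != length(pred))
        stop("gold and pred sentence counts differ: ", length(g$gold),
             " vs ", length(pred))
      labs <- unique(unlist(g$gold))
      kinds <- c(if (any(grepl("NEG|NSCO", labs))) "negation",
                 if (any(grepl("UNC|USCO", labs))) "uncertainty")
      if (length(kinds) == 0L) kinds <- c("negation", "uncertainty")
      report <- label_report(g$gold, pred, label_alphabet(kinds))
      out <- config$out %||% "report.json"
      write_label_report(report, out)
      print(report)
      invisible(list(report = out))
    },
    iaa = {
      a <- load_corpus(config$a, dialect = config$dialect)
      b <- load_corpus(config$b, dialect = config$dialect)
      rep_ <- iaa(a, b, level = config$level %||% "token")
      out <- config$out %||% "iaa.json"
      jsonlite::write_json(rep_, out, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      print(rep_)
      invisible(list(report = out))
    })
}
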