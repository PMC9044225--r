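#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run an expression under a fixed RNG seed, restoring global RNG state after.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seed derivation: one user-facing seed fans out to
# independent streams per component. Kept below 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 48271 + h * 16807 + 12345) %% 2147483587)
}

nsc_log <- function(..., level = "info") {
  threshold <- getOption("negscope.log_level", "info")
  ranks <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  if (ranks[[level]] >= ranks[[threshold]]) {
    message(sprintf("[negscope:%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

round_half_even <- function(x, digits = 2L) round(x, digits)
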