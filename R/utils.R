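# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field, integer = FALSE) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x) || any(x <= 0))
    stop_field(field, "must be positive")
  if (integer && any(x != floor(x)))
    stop_field(field, "must be whole numbers")
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, comment.char = "",
                    colClasses = "character", ...)
}
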