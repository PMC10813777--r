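#' @keywords internal
"_PACKAGE"

# Derive a child seed from a root seed and a small stage offset, kept inside
# the 32-bit integer range R requires for set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 7919 * as.double(offset)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

warn_ <- function(...) warning(sprintf(...), call. = FALSE)

# Evaluate an expression with a locally seeded RNG, restoring the caller's
# RNG state afterwards so library code never disturbs user-level streams.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Writers share one convention: UTF-8, LF, tab-separated, full precision.
write_tsv_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

format_full <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    vapply(x, function(v) {
      if (is.na(v)) "NA" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
    }, character(1))
  } else {
    as.character(x)
  }
}

# Tab-separated writer for data frames (full float precision, LF endings).
write_tsv_df <- function(df, path) {
  cells <- vapply(seq_along(df), function(j) format_full(df[[j]]),
                  character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  body <- apply(cells, 1L, paste, collapse = "\t")
  write_tsv_lines(c(paste(names(df), collapse = "\t"), body), path)
}
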