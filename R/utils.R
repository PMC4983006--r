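# Shared internal helpers.

# Round half away from zero, the display convention used for all reported
# percentages (stats::round() rounds half to even, which would print 0.25 -> 0.2).
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Read a header-bearing TSV without type mangling.
read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", "."),
                    colClasses = NA, comment.char = "")
}

write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.list(df2[[j]])) {
      df2[[j]] <- vapply(df2[[j]], function(v) paste(v, collapse = ","), "")
    }
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = ".")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
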