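# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# With seed = NULL the global RNG stream is used unchanged, so callers
# can still be made reproducible by an outer set.seed().
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# scalar checks -------------------------------------------------------------

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

check_positive <- function(x, name, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && x > 0 &&
    (is.finite(x) || (allow_inf && is.infinite(x)))
  if (!ok) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  x
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name),
         call. = FALSE)
  }
  x
}

# TSV writers with a single '#' provenance header ---------------------------

write_tsv_commented <- function(df, path, header_fields) {
  hdr <- paste0("# ", paste(sprintf("%s=%s", names(header_fields),
                                    vapply(header_fields, format, "")),
                            collapse = " "))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}
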