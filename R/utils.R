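#' @keywords internal
"_PACKAGE"

#' Derive a child seed from a global seed
#'
#' All stochastic generators in the package take one integer seed; stages that
#' need several independent streams derive child seeds deterministically so a
#' single global seed reproduces a whole run.
#'
#' @param seed integer global seed.
#' @param index integer stream index (>= 1).
#' @return An integer seed below 2^31.
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  # LCG-style mixing; keeps results in valid 32-bit integer range
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647)
}

# evaluate `code` under `seed` without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Welch two-sample t-test tolerant of zero-variance groups.
# Returns list(statistic, df, p.value); identical degenerate groups give
# t = 0, p = 1 rather than an error.
welch_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    return(list(statistic = NA_real_, df = NA_real_, p.value = NA_real_,
                note = "group with < 2 observations cannot be tested"))
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx + vy == 0) {
    d <- mean(x) - mean(y)
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                df = length(x) + length(y) - 2,
                p.value = if (d == 0) 1 else 0))
  }
  tt <- stats::t.test(x, y)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

# write a data.frame as TSV with '#'-prefixed provenance header lines
write_tsv_prov <- function(df, path, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# myodyn %s",
                     as.character(utils::packageVersion("myodyn"))), con)
  if (length(params)) {
    kv <- vapply(names(params), function(k)
      sprintf("# %s: %s", k, paste(format(params[[k]]), collapse = " ")), "")
    writeLines(kv, con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_prov <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
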