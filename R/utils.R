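# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards (seed = NULL uses the current RNG stream untouched).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop_invalid("`%s` must be a single finite number in [%s, %s]", name, lo, hi)
  x
}

check_columns <- function(df, cols, where = "panel") {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_invalid("%s is missing required column(s): %s", where,
                 paste(missing, collapse = ", "))
  invisible(df)
}

# 0/1 indicator for 'woman' from a gender column that may be factor,
# character or already numeric.
woman_indicator <- function(gender) {
  if (is.numeric(gender)) return(as.numeric(gender))
  as.numeric(as.character(gender) == "woman")
}
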