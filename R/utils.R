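#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards.  All stochastic code in the
## package routes through this so that a single integer seed fixes a run.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  expr
}

## Derive a reproducible child seed from a parent seed and an index,
## kept well inside 32-bit integer range.
child_seed <- function(seed, i) {
  (as.integer(seed) * 1009L + as.integer(i) * 7919L) %% 2147483563L
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

assert_cols <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  invisible(df)
}
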