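# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# round-half-up to integer (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

# run expr with a temporary RNG state seeded by `seed`; restores the
# caller's stream afterwards so library code never clobbers user RNG
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x) && x >= 1

assert_cols <- function(df, cols, what = "data frame") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  invisible(df)
}

days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  nxt <- if (month == 12L) as.Date(sprintf("%d-01-01", year + 1L))
         else as.Date(sprintf("%d-%02d-01", year, month + 1L))
  as.integer(nxt - first)
}
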