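# Internal helpers shared across modules.

expit <- function(x) plogis(x)

# Run `expr` with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

assert_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# Format "est (lo, hi)" at a fixed number of decimals, plain ASCII minus.
fmt_ci <- function(est, lo, hi, digits = 2) {
  sprintf(
    "%.*f (%.*f, %.*f)",
    digits, est, digits, lo, digits, hi
  )
}

fmt_gbp_whole <- function(x) formatC(round(x), format = "d", big.mark = " ")
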