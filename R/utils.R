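# Classed conditions: data problems are signalled with condition classes so
# callers (and the CLI) can distinguish them from usage/programming errors.

lc_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "lynchcohort_error", "error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

is_whole <- function(x) {
  is.numeric(x) & is.finite(x) & x == trunc(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a private RNG stream, restoring the caller's stream after
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
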