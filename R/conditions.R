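# Classed conditions so callers can programmatically distinguish failure modes.

abort_ws <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "wishartscore_error")))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort_ws("domain_error",
             sprintf("`%s` must be a single integer >= %d (got %s)",
                     name, min, deparse(substitute(x))))
  }
  as.integer(x)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's random number
#' generator state afterwards, so stochastic operations never leak into (or
#' depend on) the global RNG stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_ws("seed_error", "an explicit single integer `seed` is required")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
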