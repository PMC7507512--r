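# Internal helpers: classed conditions and seeded evaluation.

fm_stop <- function(class, msg, ..., call. = FALSE) {
  stop(structure(
    class = c(class, "fm_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}

fm_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
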