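# internal validation and RNG helpers

.check_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  ok <- if (open) x > 0 && x < 1 else x >= 0 && x <= 1
  if (!ok) stop(sprintf("'%s' must lie in %s", name,
                        if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  x
}

.check_pos_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  x
}

.check_n <- function(n, name = "n") {
  if (!is.numeric(n) || any(is.na(n)) || any(n < 1) ||
      any(abs(n - round(n)) > 1e-8))
    stop(sprintf("'%s' must be a positive integer", name), call. = FALSE)
  as.numeric(round(n))
}

# run `expr` under a temporary seed, restoring the caller's RNG state;
# seed = NULL leaves the global stream untouched (draws still advance it)
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
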