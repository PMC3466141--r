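# internal helpers shared across modules

mq_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "matchqual_error"), ...)
}

# run code with a locally seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# derive a per-item seed from a base seed, staying inside 32-bit range
derive_seed <- function(seed, i) {
  if (is.null(seed)) {
    return(NULL)
  }
  as.integer((as.numeric(seed) + 9973 * as.numeric(i)) %% 2147483563L) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# numeric tolerance for comparing midrank sums (multiples of 0.5)
STAT_TOL <- 1e-8
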