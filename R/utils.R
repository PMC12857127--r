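`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

# log(1 - exp(x)) for x <= 0, accurate near both ends.
log1mexp <- function(x) {
  stopifnot(all(x <= 0))
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
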