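# Internal helpers shared across modules.

# Evaluate `code` under a temporary seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
withSeed <- function(seed, code) {
    if (is.null(seed) || is.na(seed)) return(force(code))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    force(code)
}

asSeed <- function(seed) {
    if (is.null(seed)) NA_integer_ else as.integer(seed)
}

# Derive a stream of per-run seeds from a master seed; values stay < 2^31.
deriveSeed <- function(seed, counter) {
    as.integer((as.double(seed) * 100003 + counter * 7919) %% 2147483647)
}

stopIfNot <- function(cond, msg) {
    if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
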