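# Run expr under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# Truncate (not round) towards zero at `digits` decimals.
truncateDecimals <- function(x, digits = 2) {
    trunc(x * 10^digits) / 10^digits
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
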