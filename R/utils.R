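## Internal helpers.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All seeded package functions go through this so a
# library call never clobbers a user's random stream.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    expr
}

# Single finite numeric scalar check
assertScalar <- function(x, name, lo = -Inf, hi = Inf) {
    if (length(x) != 1 || !is.finite(x) || x < lo || x > hi)
        stop(sprintf("'%s' must be a single finite value in [%s, %s]",
                     name, format(lo), format(hi)), call. = FALSE)
    invisible(x)
}
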