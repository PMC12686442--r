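## Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# With seed = NULL the code runs on the ambient RNG stream.
.withSeed <- function(seed, code) {
    if (is.null(seed))
        return(code)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    code
}

.jaccard <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0L) return(0)
    length(intersect(a, b)) / u
}

# Standard two-sample / one-sample t machinery with explicit handling of the
# degenerate zero-variance contract: equal means -> t = 0, p = 1; unequal
# means -> the limiting |t| = Inf, p = 0 (callers flag these rows).
.safeT <- function(diff, se, df) {
    t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
    p <- ifelse(se > 0, 2 * stats::pt(-abs(t), df),
                ifelse(diff == 0, 1, 0))
    list(t = t, p = p)
}

.stopIfNot <- function(ok, ...) {
    if (!isTRUE(ok)) stop(..., call. = FALSE)
}
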