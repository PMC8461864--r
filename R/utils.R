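# Run expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    expr
}

asCount <- function(x, what) {
    if (length(x) != 1L || is.na(x) || x < 0 || x != as.integer(x))
        stop(what, " must be a single non-negative integer", call. = FALSE)
    as.integer(x)
}
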