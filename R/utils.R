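#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so
#' library code never disturbs the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# seed arithmetic kept inside 32-bit integer range
.deriveSeed <- function(base, offset) {
    as.integer((as.numeric(base) + as.numeric(offset)) %% .Machine$integer.max)
}
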