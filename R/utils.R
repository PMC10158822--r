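## Run code under a local RNG seed without disturbing the caller's stream.
## All exported stochastic functions route their randomness through here so
## that a fixed seed gives identical output regardless of global RNG state.
withSeed <- function(seed, code) {
    if (!is.null(seed) && !is.na(seed)) {
        had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(code)
}

.assertScalarNumber <- function(x, name, positive = FALSE, nonneg = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
        stop(sprintf("'%s' must be a single number", name), call. = FALSE)
    if (positive && x <= 0)
        stop(sprintf("'%s' must be > 0", name), call. = FALSE)
    if (nonneg && x < 0)
        stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
    invisible(x)
}

.matchGenome <- function(genome) {
    match.arg(genome, c("nuclear", "mitochondrial"))
}

.matchLibrary <- function(library) {
    match.arg(toupper(library), c("DSP", "SSP"))
}

.unitFor <- function(library) if (library == "DSP") "bp" else "nt"
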