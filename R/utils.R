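# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded helpers do not perturb the global stream.
.withSeed <- function(seed, code) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    code
}

# Deterministic sub-seed derivation; keeps results below 2^31.
.subSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

.assertCount <- function(x, name, min = 1L) {
    if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
        stop(sprintf("invalid config: '%s' must be a single integer >= %d",
                     name, min))
    as.integer(x)
}
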