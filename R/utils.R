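### Internal helpers: seed scoping, log-normal parameterisation, Wilson CI.

## Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG afterwards.  A NULL/NA seed evaluates `code` in the
## ambient RNG stream (so nested simulator calls share one stream).
.withSeed <- function(seed, code) {
    if (is.null(seed) || length(seed) == 0L || is.na(seed))
        return(force(code))
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
        if (had)
            assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(as.integer(seed))
    force(code)
}

## Deterministic sub-stream seeds drawn from the current stream, so adding
## later units never perturbs earlier ones.
.childSeeds <- function(n) {
    sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

## meanlog/sdlog of a log-normal with given arithmetic mean and CV.
.lnormPars <- function(mean, cv) {
    sdlog <- sqrt(log1p(cv^2))
    list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

## One multiplicative log-normal noise factor with unit mean and given CV.
.noiseFactor <- function(cv, n = 1L) {
    if (cv <= 0)
        return(rep(1, n))
    p <- .lnormPars(1, cv)
    stats::rlnorm(n, p$meanlog, p$sdlog)
}

## Wilson score interval for a binomial proportion.
.wilson <- function(k, n, conf = 0.95) {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    p <- k / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    c(max(0, centre - half), min(1, centre + half))
}

## Seed default resolution for simulator calls: an explicit argument wins,
## otherwise the SimModel's own seed slot (if set), otherwise NULL.
.resolveSeed <- function(seed, model = NULL) {
    if (!is.null(seed) && !is.na(seed))
        return(as.integer(seed))
    if (!is.null(model) && !is.na(model@seed))
        return(model@seed)
    NULL
}
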