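## Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream. All generators route their randomness through this, which is
## what makes them pure functions of (config, seed).
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
    force(expr)
}

## drop spikes closer than the text-format precision (keeps strict order)
dedupeTimes <- function(t) {
    if (length(t) < 2) return(t)
    t[c(TRUE, diff(t) > 2e-6)]
}

msToS <- function(ms) ms / 1000
sToMs <- function(s) s * 1000

## scalar-numeric argument check
assertNum <- function(x, name, lower = -Inf, upper = Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
        stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                     format(lower), format(upper)), call. = FALSE)
    invisible(x)
}

## mean +/- SEM and median [Q1-Q3] in one row; quantiles use linear
## interpolation (type 7), matching the reporting style of the tables.
summaryRow <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    q <- if (n) stats::quantile(x, c(.25, .5, .75), names = FALSE, type = 7)
         else rep(NA_real_, 3)
    data.frame(n = n,
               mean = if (n) mean(x) else NA_real_,
               sem  = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
               median = q[2], q1 = q[1], q3 = q[3])
}
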