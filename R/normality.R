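#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness and kurtosis into the K2
#' statistic, chi-squared with 2 df under normality. This is the gate used
#' throughout the package to route group comparisons to parametric or
#' rank-based tests. Requires n >= 8 (the kurtosis standardization is
#' undefined below that); smaller samples return NA and callers fall back
#' to their parametric default.
#'
#' @param x numeric sample.
#' @return list: statistic (K2), p, z_skew, z_kurt, n.
#' @export
dagostinoPearson <- function(x) {
    x <- x[is.finite(x)]
    n <- length(x)
    if (n < 8 || stats::sd(x) == 0)
        return(list(statistic = NA_real_, p = NA_real_, z_skew = NA_real_,
                    z_kurt = NA_real_, n = n))
    m <- mean(x)
    m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
    b1 <- m3 / m2^1.5                       # skewness (population moments)
    b2 <- m4 / m2^2                         # kurtosis

    ## skewness z (D'Agostino 1970)
    y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
    beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
        ((n - 2) * (n + 5) * (n + 7) * (n + 9))
    W2 <- -1 + sqrt(2 * (beta2 - 1))
    delta <- 1 / sqrt(0.5 * log(W2))
    alpha <- sqrt(2 / (W2 - 1))
    ya <- y / alpha
    z1 <- delta * log(ya + sqrt(ya^2 + 1))

    ## kurtosis z (Anscombe & Glynn 1983)
    E <- 3 * (n - 1) / (n + 1)
    varb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
    xs <- (b2 - E) / sqrt(varb2)
    sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
        sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
    A <- 6 + 8 / sqrtbeta1 *
        (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
    term <- (1 - 2 / A) / (1 + xs * sqrt(2 / (A - 4)))
    z2 <- ((1 - 2 / (9 * A)) - sign(term) * abs(term)^(1 / 3)) /
        sqrt(2 / (9 * A))

    k2 <- z1^2 + z2^2
    list(statistic = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
         z_skew = z1, z_kurt = z2, n = n)
}
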