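## Independent oracles, written directly from the model definitions and
## kept free of the package's own numerical code paths.

## Published parameter set used throughout the tests.
truthParams <- function() ddAhbABParams()
truthVector <- c(Km1 = 11.74, Vmax1 = 44.63, Km2 = 9.94, Vmax2 = 33.22,
                 Ki = 1.77)

## Direct closed-form evaluation of the rate laws (spreadsheet-level
## arithmetic, independent of rateV1/rateV2).
oracleFreeS3 <- function(S3, Ki, E0) {
    b <- E0 + S3 + Ki
    S3 - (b - sqrt(b^2 - 4 * E0 * S3)) / 2
}

oracleRate1 <- function(Km1, Vmax1, Km2, Ki, S1, S2, S3, E, Eref = 2.3) {
    f3 <- if (S3 > 0) oracleFreeS3(S3, Ki, E) else 0
    Vmax1 * (E / Eref) * S1 / (Km1 * (1 + S2 / Km2 + f3 / Ki) + S1)
}

oracleRate2 <- function(Km1, Vmax2, Km2, Ki, S1, S2, S3, E, Eref = 2.3) {
    f3 <- if (S3 > 0) oracleFreeS3(S3, Ki, E) else 0
    Vmax2 * (E / Eref) * S2 / (Km2 * (1 + S1 / Km1 + f3 / Ki) + S2)
}

## Fixed-step classical fourth-order Runge-Kutta integration of the
## cascade, with its own right-hand side; used as the trajectory oracle.
oracleRK4 <- function(pars, init, tEnd, h = 1e-4, E = 2.3, Eref = 2.3) {
    Km1 <- pars[["Km1"]]; V1 <- pars[["Vmax1"]] * E / Eref
    Km2 <- pars[["Km2"]]; V2 <- pars[["Vmax2"]] * E / Eref
    Ki <- pars[["Ki"]]
    rhs <- function(y) {
        s1 <- y[1L]; s2 <- y[2L]; s3 <- y[3L]
        f3 <- if (s3 > 0) {
            b <- E + s3 + Ki
            s3 - (b - sqrt(b * b - 4 * E * s3)) / 2
        } else 0
        inh <- f3 / Ki
        v1 <- if (s1 > 0) V1 * s1 / (Km1 * (1 + s2 / Km2 + inh) + s1) else 0
        v2 <- if (s2 > 0) V2 * s2 / (Km2 * (1 + s1 / Km1 + inh) + s2) else 0
        c(-v1, v1 - v2, v2)
    }
    n <- round(tEnd / h)
    y <- init
    for (i in seq_len(n)) {
        k1 <- rhs(y)
        k2 <- rhs(y + h / 2 * k1)
        k3 <- rhs(y + h / 2 * k2)
        k4 <- rhs(y + h * k3)
        y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    y
}

## Grid-search Nernst midpoint oracle: for each candidate Em the two
## asymptotes enter linearly, so they are profiled out by ordinary linear
## least squares and Em is taken from the best grid point.
oracleNernstGridEm <- function(E, A, grid = seq(-300, 100, by = 0.1),
                               n = 1, temperature = 298.15) {
    beta <- n * 96485.33212 / (8.31446262 * temperature * 1000)
    best <- c(Em = NA_real_, rss = Inf)
    for (em in grid) {
        fred <- 1 / (1 + exp(beta * (E - em)))
        X <- cbind(1 - fred, fred)
        co <- .lm.fit(X, A)
        rss <- sum(co$residuals^2)
        if (rss < best[["rss"]]) best <- c(Em = em, rss = rss)
    }
    best[["Em"]]
}
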