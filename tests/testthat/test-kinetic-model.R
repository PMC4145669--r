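test_that("rate laws obey the zero-substrate and half-saturation identities", {
    p <- truthParams()
    expect_identical(rateV1(p, c(0, 7, 3)), 0)
    expect_identical(rateV2(p, c(7, 0, 3)), 0)
    ## with no competitor and no product the rate is the bare hyperbola
    expect_equal(rateV1(p, c(p@Km1, 0, 0)), p@Vmax1 / 2)
    expect_equal(rateV2(p, c(0, p@Km2, 0)), p@Vmax2 / 2)
})

test_that("rates match the direct closed-form evaluation oracle", {
    p <- truthParams()
    ## frozen from the closed-form oracle at S = (10, 5, 2) uM, E = 2.3 uM
    expect_equal(rateV1(p, c(10, 5, 2)), 12.7428482784, tolerance = 1e-9)
    expect_equal(rateV2(p, c(10, 5, 2)), 5.6013275582, tolerance = 1e-9)
    grid <- expand.grid(S1 = c(0.5, 8, 23), S2 = c(0, 4, 15),
                        S3 = c(0, 1.5, 9), E = c(1.1, 2.3))
    for (i in seq_len(nrow(grid))) {
        g <- grid[i, ]
        expect_equal(
            rateV1(p, c(g$S1, g$S2, g$S3), enzymeConc = g$E),
            oracleRate1(p@Km1, p@Vmax1, p@Km2, p@Ki, g$S1, g$S2, g$S3, g$E),
            tolerance = 1e-12)
        expect_equal(
            rateV2(p, c(g$S1, g$S2, g$S3), enzymeConc = g$E),
            oracleRate2(p@Km1, p@Vmax2, p@Km2, p@Ki, g$S1, g$S2, g$S3, g$E),
            tolerance = 1e-12)
    }
})

test_that("invalid parameters and states are rejected", {
    p <- truthParams()
    expect_error(RateParameters(-1, 44.63, 9.94, 33.22, 1.77), "positive")
    expect_error(RateParameters(11.74, 44.63, 9.94, 33.22, Inf), "finite|positive")
    expect_error(rateV1(p, c(-1, 0, 0)), "non-negative")
    expect_error(rateV1(p, c(1, 0, 0), enzymeConc = 0), "positive")
})

test_that("each rate rises with its substrate and falls with competitors", {
    p <- truthParams()
    s1 <- seq(0.5, 25, length.out = 9)
    v <- vapply(s1, function(s) rateV1(p, c(s, 4, 2)), numeric(1))
    expect_true(all(diff(v) > 0))
    s2 <- seq(0, 20, length.out = 9)
    v <- vapply(s2, function(s) rateV1(p, c(10, s, 2)), numeric(1))
    expect_true(all(diff(v) < 0))
    s3 <- seq(0, 20, length.out = 9)
    v <- vapply(s3, function(s) rateV1(p, c(10, 4, s)), numeric(1))
    expect_true(all(diff(v) < 0))
    v <- vapply(s2[-1], function(s) rateV2(p, c(10, s, 2)), numeric(1))
    expect_true(all(diff(v) > 0))
    v <- vapply(s1, function(s) rateV2(p, c(s, 4, 2)), numeric(1))
    expect_true(all(diff(v) < 0))
    v <- vapply(s3, function(s) rateV2(p, c(10, 4, s)), numeric(1))
    expect_true(all(diff(v) < 0))
})

test_that("rates reduce to the classical competitive and hyperbolic limits", {
    p <- truthParams()
    noKi <- RateParameters(p@Km1, p@Vmax1, p@Km2, p@Vmax2, Ki = 1e12)
    ## product absent, huge Ki: two-substrate competitive form
    expect_equal(rateV1(noKi, c(10, 5, 0)),
                 p@Vmax1 * 10 / (p@Km1 * (1 + 5 / p@Km2) + 10),
                 tolerance = 1e-9)
    expect_equal(rateV2(noKi, c(10, 5, 0)),
                 p@Vmax2 * 5 / (p@Km2 * (1 + 10 / p@Km1) + 5),
                 tolerance = 1e-9)
    ## single substrate: Michaelis-Menten hyperbola
    expect_equal(rateV1(noKi, c(10, 0, 0)),
                 p@Vmax1 * 10 / (p@Km1 + 10), tolerance = 1e-9)
})

test_that("simulated trajectories are monotone, conserving and non-negative", {
    p <- truthParams()
    z <- simulateTimeCourse(p, c(0, 0, 0))
    expect_true(all(concentrations(z) == 0))
    tc <- simulateTimeCourse(p, c(23, 0, 0))
    st <- concentrations(tc)
    expect_true(all(st >= 0))
    expect_true(all(diff(st[, "S1"]) <= 1e-9))
    expect_true(all(diff(st[, "S3"]) >= -1e-9))
    ## the intermediate rises then falls through one interior maximum
    s2 <- st[, "S2"]
    imax <- which.max(s2)
    expect_gt(imax, 1L)
    expect_lt(imax, length(s2))
    expect_true(all(diff(s2[seq_len(imax)]) > -1e-9))
    expect_true(all(diff(s2[imax:length(s2)]) < 1e-9))
    expect_lt(conservationResidual(tc), 1e-6)
    expect_error(simulateTimeCourse(p, c(23, 0, 0), times = c(1, 2, 3)),
                 "from 0")
    expect_error(simulateTimeCourse(p, c(23, 0, 0), times = c(0, 2, 2)),
                 "increasing")
})

test_that("adaptive trajectories match a fine-step Runge-Kutta oracle", {
    p <- truthParams()
    tc <- simulateTimeCourse(p, c(23, 0, 0), times = c(0, 2, 10))
    ref <- oracleRK4(truthVector, c(23, 0, 0), tEnd = 10, h = 1e-4)
    got <- concentrations(tc)[3L, ]
    expect_lt(max(abs(got - ref) / pmax(abs(ref), 1e-8)), 1e-6)
})

test_that("conservation residual measures departures from a closed system", {
    p <- truthParams()
    tc <- simulateTimeCourse(p, c(23, 0, 0))
    st <- concentrations(tc)
    st[5L, 2L] <- st[5L, 2L] + 1
    bumped <- TimeCourse(timePoints(tc), st)
    expect_equal(conservationResidual(bumped), 1, tolerance = 1e-9)
    ## on noisy data the residual is of the order of the injected noise
    noisy <- genTimeCourse(p, nReplicates = 1L,
                           noise = noiseModel("multiplicative_gaussian",
                                              0.05, seed = 11))[[1L]]
    r <- conservationResidual(noisy)
    expect_gt(r, 0.05)   # 5% of ~23 uM spread over three species
    expect_lt(r, 10)
})
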