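test_that("the Nernst curve obeys its midpoint and decade identities", {
    pars <- NernstFit(Em = -98, Aox = 0.10, Ared = 0.35)
    expect_equal(nernstAbsorbance(-98, pars), (0.10 + 0.35) / 2)
    ## three decades below the midpoint the couple is within 0.1% of fully
    ## reduced (one decade per ~59.16 mV at 25 C, n = 1)
    decade <- log(10) * 8.31446262 * 298.15 * 1000 / 96485.33212
    expect_equal(decade, 59.16, tolerance = 1e-4)
    A <- nernstAbsorbance(-98 - 3 * decade, pars)
    fracRed <- (A - pars@Aox) / (pars@Ared - pars@Aox)
    expect_equal(fracRed, 1 / (1 + 1e-3), tolerance = 1e-9)
    ## monotone, with the correct asymptotes
    E <- seq(-400, 250, by = 10)
    vals <- nernstAbsorbance(E, pars)
    expect_true(all(diff(vals) < 0))
    expect_equal(nernstAbsorbance(-1e4, pars), pars@Ared, tolerance = 1e-9)
    expect_equal(nernstAbsorbance(1e4, pars), pars@Aox, tolerance = 1e-9)
})

test_that("a noiseless titration refits its midpoint almost exactly", {
    curve <- genTitration(Em = -98, Aox = 0.1, Ared = 0.35)
    fit <- fitNernst(curve)
    expect_true(converged(fit))
    expect_equal(midpointPotential(fit), -98, tolerance = 1e-6)
    expect_equal(fit@Aox, 0.1, tolerance = 1e-6)
    expect_equal(fit@Ared, 0.35, tolerance = 1e-6)
    ## direction-agnostic: an absorbance that falls on reduction fits too
    curve2 <- genTitration(Em = -98, Aox = 0.35, Ared = 0.1)
    expect_equal(midpointPotential(fitNernst(curve2)), -98,
                 tolerance = 1e-6)
})

test_that("flat titration data raise a no-transition diagnostic", {
    E <- seq(-300, 100, by = 10)
    expect_error(fitNernst(TitrationCurve(E, rep(0.2, length(E)))),
                 "transition")
})

test_that("the fitted midpoint agrees with a grid-search oracle", {
    noise <- noiseModel("additive_gaussian", 0.004, seed = 19)
    curve <- genTitration(Em = -98, Aox = 0.1, Ared = 0.35, noise = noise)
    fit <- fitNernst(curve)
    df <- as.data.frame(curve)
    emGrid <- oracleNernstGridEm(df$potential_mV_NHE, df$absorbance)
    expect_lt(abs(midpointPotential(fit) - emGrid), 0.1)
})

test_that("the Nernst fit is translation and scale equivariant", {
    noise <- noiseModel("additive_gaussian", 0.003, seed = 23)
    curve <- genTitration(Em = -98, Aox = 0.1, Ared = 0.35, noise = noise)
    fit <- fitNernst(curve)
    delta <- 37.5
    shifted <- TitrationCurve(curve@potentials + delta, curve@absorbances)
    fitS <- fitNernst(shifted)
    expect_equal(midpointPotential(fitS), midpointPotential(fit) + delta,
                 tolerance = 1e-6)
    cc <- 2.7
    scaled <- TitrationCurve(curve@potentials, cc * curve@absorbances)
    fitC <- fitNernst(scaled)
    expect_equal(midpointPotential(fitC), midpointPotential(fit),
                 tolerance = 1e-6)
    expect_equal(fitC@Aox, cc * fit@Aox, tolerance = 1e-6)
    expect_equal(fitC@Ared, cc * fit@Ared, tolerance = 1e-6)
})

test_that("the midpoint estimate is unbiased under titration noise", {
    ems <- vapply(1:100, function(s) {
        curve <- genTitration(Em = -98, Aox = 0.1, Ared = 0.35,
                              noise = noiseModel("additive_gaussian",
                                                 0.005, seed = 500 + s))
        midpointPotential(fitNernst(curve))
    }, numeric(1))
    expect_lt(abs(mean(ems) + 98), 3)
    expect_gt(sd(ems), 0)
})
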