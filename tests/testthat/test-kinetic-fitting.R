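test_that("a fit of self-consistent data returns the generating parameters", {
    p <- truthParams()
    tc <- simulateTimeCourse(p, c(23, 0, 0))
    fit <- fitTimeCourse(tc, guess = p, multistart = 1L)
    expect_true(converged(fit))
    expect_lt(fit@rss, 1e-12)
    expect_equal(paramVector(estimates(fit)), truthVector, tolerance = 1e-6)
    expect_lte(fit@rss, fit@startObjective)
    expect_identical(fit@nObs, 48L)
})

test_that("perturbed starting guesses recover the generating parameters", {
    p <- truthParams()
    tc <- simulateTimeCourse(p, c(23, 0, 0))
    set.seed(3)
    g <- truthVector * runif(5, 0.5, 1.5)
    guess <- RateParameters(g[1], g[2], g[3], g[4], g[5])
    fit <- fitTimeCourse(tc, guess, multistart = 5L, seed = 3L)
    expect_true(converged(fit))
    rel <- abs(paramVector(estimates(fit)) - truthVector) / truthVector
    expect_lt(max(rel), 1e-4)
    expect_lte(fit@rss, fit@startObjective)
})

test_that("degenerate fitting inputs are rejected", {
    p <- truthParams()
    short <- simulateTimeCourse(p, c(23, 0, 0), times = c(0, 1, 2, 5, 10))
    expect_error(fitTimeCourse(short, p), "at least 6")
    allZero <- TimeCourse(defaultKineticTimes(),
                          matrix(0, 16, 3))
    expect_error(fitTimeCourse(allZero, p), "non-zero")
    tc <- simulateTimeCourse(p, c(23, 0, 0))
    other <- simulateTimeCourse(p, c(23, 0, 0),
                                times = defaultKineticTimes(tFirst = 0.4))
    expect_error(fitTimeCourse(list(tc, other), p), "common time grid")
})

test_that("the cascade model is directional: species relabelling degrades the fit", {
    p <- truthParams()
    tc <- simulateTimeCourse(p, c(23, 0, 0))
    st <- concentrations(tc)
    reversed <- TimeCourse(timePoints(tc), st[, c(3L, 2L, 1L)],
                           enzymeConc = enzymeConc(tc))
    ## swapping the step parameters does NOT compensate reversing the data:
    swapped <- RateParameters(p@Km2, p@Vmax2, p@Km1, p@Vmax1, p@Ki)
    fitFwd <- fitTimeCourse(tc, p, multistart = 1L)
    fitRev <- suppressWarnings(
        fitTimeCourse(reversed, swapped, multistart = 1L, maxEval = 60L))
    expect_lt(fitFwd@rss, 1e-12)
    expect_gt(fitRev@rss, 1)
})

test_that("linearized errors vanish in the zero-residual limit", {
    p <- truthParams()
    tc <- simulateTimeCourse(p, c(23, 0, 0))
    fit <- fitTimeCourse(tc, p, multistart = 1L)
    se <- estimateUncertainty(fit, tc, method = "linearized")
    expect_true(all(is.finite(se)))
    expect_true(all(se < 1e-3 * paramVector(estimates(fit))))
})

test_that("bootstrap uncertainty is seeded, guarded and sane", {
    p <- truthParams()
    tc <- simulateTimeCourse(p, c(23, 0, 0))
    fit <- fitTimeCourse(tc, p, multistart = 1L)
    expect_error(estimateUncertainty(fit, tc, method = "bootstrap",
                                     nBoot = 0L), "nBoot")
    bad <- fit
    bad@converged <- FALSE
    expect_error(estimateUncertainty(bad, tc), "converged")
    ## at low noise the bootstrap and linearized errors agree in magnitude
    reps <- genTimeCourse(p, noise = noiseModel("multiplicative_gaussian",
                                                0.01, seed = 5))
    nf <- fitTimeCourse(reps, p, multistart = 1L)
    lin <- estimateUncertainty(nf, reps, method = "linearized")
    boot <- estimateUncertainty(nf, reps, method = "bootstrap",
                                nBoot = 20L, seed = 7L)
    boot2 <- estimateUncertainty(nf, reps, method = "bootstrap",
                                 nBoot = 20L, seed = 7L)
    expect_equal(as.numeric(boot), as.numeric(boot2))  # determinism
    ratio <- as.numeric(boot) / as.numeric(lin)
    expect_true(all(is.finite(ratio) & ratio > 0))
    expect_lt(max(abs(log(ratio))), log(8))
})

test_that("goodness of fit decomposes the pooled RMSE over species", {
    p <- truthParams()
    tc <- simulateTimeCourse(p, c(23, 0, 0))
    fit <- fitTimeCourse(tc, p, multistart = 1L)
    g <- goodnessOfFit(fit)
    expect_true(all(g$perSpecies < 1e-7))
    expect_lt(g$total, 1e-7)
    ## constructed residuals: unit residual everywhere gives unit RMSE
    unitFit <- fit
    unitFit@residuals <- setNames(rep(1, 48),
                                  rep(c("S1", "S2", "S3"), each = 16L))
    g1 <- goodnessOfFit(unitFit)
    expect_equal(unname(g1$perSpecies), c(1, 1, 1))
    expect_equal(g1$total, 1)
    ## sum-of-squares decomposition is exact
    noisyFit <- fit
    noisyFit@residuals <- setNames(rnorm(48, sd = 0.3),
                                   rep(c("S1", "S2", "S3"), each = 16L))
    g2 <- goodnessOfFit(noisyFit)
    expect_equal(sum(g2$perSpecies^2) * 16, g2$total^2 * 48,
                 tolerance = 1e-12)
})

test_that("estimate spread shrinks as observation noise decreases", {
    p <- truthParams()
    errAt <- function(cv, seeds) {
        vapply(seeds, function(s) {
            reps <- genTimeCourse(p, noise = noiseModel(
                "multiplicative_gaussian", cv, seed = s))
            f <- fitTimeCourse(reps, p, multistart = 1L, maxEval = 100L)
            abs(paramVector(estimates(f))[["Ki"]] - truthVector[["Ki"]])
        }, numeric(1))
    }
    ## paired by seed: the same standardized noise draws, scaled by the CV,
    ## so shrinkage is tested against matched perturbations
    lo <- errAt(0.005, 21:24)
    hi <- errAt(0.05, 21:24)
    expect_lt(median(lo), median(hi))
})
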