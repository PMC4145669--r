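test_that("difference spectra subtract point-wise and refuse mismatched grids", {
    grid <- seq(520, 620, by = 0.5)
    pair <- genHaemochromePair(556, grid = grid)
    d <- differenceSpectrum(pair$reduced, pair$oxidized)
    expect_s4_class(d, "DifferenceSpectrum")
    expect_equal(absorbances(d),
                 absorbances(pair$reduced) - absorbances(pair$oxidized))
    ## identity and zero-reference cases
    same <- differenceSpectrum(pair$oxidized, pair$oxidized)
    expect_true(all(absorbances(same) == 0))
    zero <- Spectrum(grid, rep(0, length(grid)), label = "blank")
    expect_equal(absorbances(differenceSpectrum(pair$reduced, zero)),
                 absorbances(pair$reduced))
    ## linearity: difference of scaled spectra is the scaled difference
    a <- 3.2
    dA <- differenceSpectrum(Spectrum(grid, a * absorbances(pair$reduced)),
                             Spectrum(grid, a * absorbances(pair$oxidized)))
    expect_equal(absorbances(dA), a * absorbances(d), tolerance = 1e-12)
    other <- Spectrum(seq(520, 620, by = 1), rep(0, 101))
    expect_error(differenceSpectrum(pair$reduced, other), "grid")
})

test_that("the alpha-band apex is located to sub-grid precision", {
    ## 1 nm grid, haem-b band at 556 nm
    pair <- genHaemochromePair(556, grid = seq(520, 620, by = 1))
    d <- differenceSpectrum(pair$reduced, pair$oxidized)
    apex <- findAlphaPeak(d)
    expect_lt(abs(as.numeric(apex) - 556), 0.1)
    expect_gt(attr(apex, "height"), 0)
    ## sweep of generator centres on the 0.5 nm grid
    for (centre in seq(548, 560, by = 1.5)) {
        pr <- genHaemochromePair(centre)
        ap <- findAlphaPeak(differenceSpectrum(pr$reduced, pr$oxidized))
        expect_lt(abs(as.numeric(ap) - centre), 0.2)
    }
})

test_that("flat or monotone windows raise a no-peak diagnostic", {
    grid <- seq(520, 620, by = 0.5)
    flat <- new("DifferenceSpectrum", wavelengths = grid,
                absorbances = rep(0.05, length(grid)),
                label = "flat", provenance = c("r", "o"))
    expect_error(findAlphaPeak(flat), "no alpha band|flat|monotone")
    ramp <- new("DifferenceSpectrum", wavelengths = grid,
                absorbances = seq(0, 1, length.out = length(grid)),
                label = "ramp", provenance = c("r", "o"))
    expect_error(findAlphaPeak(ramp), "monotone|flat")
    expect_error(findAlphaPeak(flat, window = c(500, 560)), "beyond")
})

test_that("haem classification reproduces the reported type assignments", {
    expect_identical(classifyHaem(556), "haem_b")
    expect_identical(classifyHaem(554), "intermediate")
    expect_identical(classifyHaem(550), "haem_c")
    ## boundary wavelengths belong to the outer classes
    expect_identical(classifyHaem(555), "haem_b")
    expect_identical(classifyHaem(551), "haem_c")
    ## total on the admissible window, refused outside it
    for (wl in seq(540, 575, by = 0.5))
        expect_true(classifyHaem(wl) %in%
                        c("haem_b", "haem_c", "intermediate"))
    expect_error(classifyHaem(539.9), "refused")
    expect_error(classifyHaem(580), "refused")
})

test_that("generated band centres classify exactly per the thresholds", {
    for (centre in seq(548, 560, by = 0.5)) {
        pr <- genHaemochromePair(centre)
        ap <- as.numeric(findAlphaPeak(differenceSpectrum(pr$reduced,
                                                          pr$oxidized)))
        want <- if (centre >= 555) "haem_b" else if (centre <= 551)
            "haem_c" else "intermediate"
        ## classify at the reported apex precision (0.01 nm) so boundary
        ## centres are not decided by interpolation round-off
        expect_identical(classifyHaem(round(ap, 2)), want)
    }
})

test_that("chromatogram peaks are assigned by retention time", {
    chrom <- genChromatogram(c(0.2, 0.3, 0.5))
    asg <- assignHplcPeaks(chrom)
    expect_identical(asg$species, c("SH", "MDSH", "DDSH"))
    expect_equal(asg$retention_time, c(16.0, 19.5, 25.0), tolerance = 0.05)
    ## integrated areas recover the generating fractions
    expect_equal(asg$area / sum(asg$area), c(0.2, 0.3, 0.5),
                 tolerance = 0.01)
    ## flat trace: nothing to assign
    flat <- Chromatogram(seq(10, 30, by = 0.02), rep(0, 1001))
    expect_identical(nrow(assignHplcPeaks(flat)), 0L)
    ## a peak 0.3 min from the reference is still matched
    near <- genChromatogram(c(0, 1, 0), centres = c(16, 19.8, 25))
    asgN <- assignHplcPeaks(near)
    expect_identical(asgN$species, "MDSH")
    ## outside the tolerance it is unassigned
    far <- genChromatogram(c(0, 1, 0), centres = c(16, 21.8, 25))
    expect_identical(assignHplcPeaks(far)$species, "unassigned")
})

test_that("peak areas convert to concentrations that close the total", {
    asg <- data.frame(species = c("SH", "MDSH", "DDSH"),
                      retention_time = c(16, 19.5, 25),
                      area = c(1, 1, 2), apex_height = c(1, 1, 2))
    v <- fractionsFromChromatogram(asg, 23)
    expect_equal(unname(v), c(5.75, 5.75, 11.5))
    expect_identical(sum(v), 23)
    one <- data.frame(species = "SH", retention_time = 16, area = 3,
                      apex_height = 1)
    expect_equal(unname(fractionsFromChromatogram(one, 23)), c(23, 0, 0))
    none <- data.frame(species = "unassigned", retention_time = 12,
                       area = 1, apex_height = 1)
    expect_error(fractionsFromChromatogram(none, 23), "assigned")
    ## noisy generator round-trip within 0.02 of the true fractions
    noisy <- genChromatogram(c(0.2, 0.3, 0.5),
                             noise = noiseModel("additive_gaussian", 0.002,
                                                seed = 9))
    frac <- fractionsFromChromatogram(assignHplcPeaks(noisy), 1)
    expect_lt(max(abs(frac - c(0.2, 0.3, 0.5))), 0.02)
})
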