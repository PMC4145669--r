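## Synthetic-data generators emulating the four assay types, so every
## analysis stage has ground-truth inputs. Each generator is a pure
## function of its arguments including the noise seed; the caller's RNG
## state is saved and restored around any seeded draws.

.applyNoise <- function(x, noise, z) {
    switch(noise@kind,
        none = x,
        multiplicative_gaussian = {
            out <- x * (1 + noise@cvOrSd * z)
            out[out < noise@floor] <- 0
            out
        },
        additive_gaussian = {
            out <- x + noise@cvOrSd * z
            out[out < noise@floor] <- 0
            out
        })
}

.withSeed <- function(seed, expr) {
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(seed)
    force(expr)
}

#' Generate synthetic progress-curve replicates
#'
#' Simulates the two-step decarboxylation model (identically to
#' [simulateTimeCourse()]) and overlays observation noise independently on
#' every concentration of every replicate. With `noise` of kind "none" the
#' replicates equal the noiseless simulation exactly. The default noise for
#' concentration data is 5% multiplicative Gaussian, a typical HPLC-MS
#' quantification spread.
#'
#' @param params A [RateParameters-class].
#' @param S0 Initial concentrations (S1, S2, S3), uM; default the standard
#'   23 uM sirohaem assay.
#' @param enzymeConc Assay enzyme concentration, uM.
#' @param times Sampling times, minutes (default [defaultKineticTimes()]).
#' @param nReplicates Number of replicates (default 3).
#' @param noise A [NoiseModel-class]; seed mandatory unless kind "none".
#' @return A list of [TimeCourse-class] replicates (`replicateId` "rep1",
#'   "rep2", ...).
#' @export
genTimeCourse <- function(params, S0 = c(23, 0, 0),
                          enzymeConc = params@Eref,
                          times = defaultKineticTimes(),
                          nReplicates = 3L,
                          noise = noiseModel("none")) {
    stopifnot(is(noise, "NoiseModel"))
    validObject(noise)
    if (nReplicates < 1L) stop("nReplicates must be >= 1", call. = FALSE)
    clean <- simulateTimeCourse(params, S0, times, enzymeConc = enzymeConc)
    states <- concentrations(clean)
    if (noise@kind == "none") {
        return(lapply(seq_len(nReplicates), function(r)
            TimeCourse(times, states, enzymeConc = enzymeConc,
                       replicateId = paste0("rep", r))))
    }
    .withSeed(noise@seed, {
        lapply(seq_len(nReplicates), function(r) {
            z <- matrix(rnorm(length(states)), nrow(states), ncol(states))
            TimeCourse(times, .applyNoise(states, noise, z),
                       enzymeConc = enzymeConc,
                       replicateId = paste0("rep", r))
        })
    })
}

#' Generate a synthetic redox titration curve
#'
#' Evaluates the two-state Nernst model ([nernstAbsorbance()]) on the given
#' potential grid and overlays observation noise (additive Gaussian is the
#' natural choice for absorbances).
#'
#' @param Em Midpoint potential, mV vs NHE.
#' @param Aox,Ared Asymptotic absorbances, AU.
#' @param potentials Applied potentials, mV vs NHE (default -300 to +100 in
#'   10 mV steps).
#' @param nElectrons Electrons of the couple (default 1).
#' @param temperature Temperature, K (default 298.15).
#' @param wavelength Observation wavelength, nm (default 529).
#' @param noise A [NoiseModel-class].
#' @return A [TitrationCurve-class].
#' @examples
#' tc <- genTitration(Em = -98, Aox = 0.1, Ared = 0.35)
#' midpointPotential(fitNernst(tc))
#' @export
genTitration <- function(Em, Aox, Ared,
                         potentials = seq(-300, 100, by = 10),
                         nElectrons = 1L, temperature = 298.15,
                         wavelength = 529,
                         noise = noiseModel("none")) {
    stopifnot(is(noise, "NoiseModel"))
    validObject(noise)
    pars <- NernstFit(Em = Em, Aox = Aox, Ared = Ared,
                      nElectrons = nElectrons, temperature = temperature)
    A <- nernstAbsorbance(potentials, pars)
    if (noise@kind != "none")
        A <- .withSeed(noise@seed,
                       .applyNoise(A, noise, rnorm(length(A))))
    TitrationCurve(potentials, A, wavelength = wavelength)
}

#' Generate a synthetic pyridine haemochrome spectrum pair
#'
#' The oxidized spectrum is a flat baseline; the reduced spectrum adds
#' Gaussian alpha and beta bands, so the reduced-minus-oxidized difference
#' has its alpha apex at `alphaCentre` in the noiseless case. Band widths
#' are Gaussian standard deviations in nm.
#'
#' @param alphaCentre Alpha-band centre, nm (556 for a b-type haem).
#' @param alphaWidth Alpha-band Gaussian sd, nm (default 6).
#' @param betaCentre Beta-band centre, nm (default 527).
#' @param betaWidth Beta-band Gaussian sd, nm (default 6).
#' @param amplitudes Band amplitudes, AU: named c(alpha, beta).
#' @param grid Wavelength grid, nm (default 520-620 nm, 0.5 nm step).
#' @param baseline Baseline absorbance, AU (default 0.1).
#' @param noise A [NoiseModel-class], applied independently to both
#'   spectra.
#' @return A list with elements `reduced` and `oxidized`
#'   ([Spectrum-class]).
#' @examples
#' pair <- genHaemochromePair(556)
#' findAlphaPeak(differenceSpectrum(pair$reduced, pair$oxidized))
#' @export
genHaemochromePair <- function(alphaCentre = 556, alphaWidth = 6,
                               betaCentre = 527, betaWidth = 6,
                               amplitudes = c(alpha = 0.05, beta = 0.03),
                               grid = seq(520, 620, by = 0.5),
                               baseline = 0.1,
                               noise = noiseModel("none")) {
    stopifnot(is(noise, "NoiseModel"), alphaWidth > 0, betaWidth > 0)
    validObject(noise)
    if (alphaCentre < min(grid) || alphaCentre > max(grid) ||
        betaCentre < min(grid) || betaCentre > max(grid))
        stop("band centres must lie inside the wavelength grid",
             call. = FALSE)
    ox <- rep(baseline, length(grid))
    red <- baseline +
        amplitudes[["alpha"]] * exp(-(grid - alphaCentre)^2 /
                                        (2 * alphaWidth^2)) +
        amplitudes[["beta"]] * exp(-(grid - betaCentre)^2 /
                                       (2 * betaWidth^2))
    if (noise@kind != "none") {
        vals <- .withSeed(noise@seed, {
            list(red = .applyNoise(red, noise, rnorm(length(grid))),
                 ox = .applyNoise(ox, noise, rnorm(length(grid))))
        })
        red <- vals$red; ox <- vals$ox
    }
    list(reduced = Spectrum(grid, red, label = "reduced"),
         oxidized = Spectrum(grid, ox, label = "oxidized"))
}

#' Generate a synthetic HPLC chromatogram
#'
#' A sum of Gaussian peaks at the tetrapyrrole reference retention times,
#' with areas proportional to the requested species fractions.
#'
#' @param fractions Three non-negative numbers summing to 1: area fractions
#'   of sirohaem, monodecarboxysirohaem, didecarboxysirohaem.
#' @param centres Peak centres, minutes (default 16.0, 19.5, 25.0).
#' @param widths Peak Gaussian sds, minutes (default 0.25 each).
#' @param grid Retention-time grid, minutes (default 10-30 min, 0.02 min
#'   step).
#' @param totalArea Total area of all peaks, AU min (default 1).
#' @param noise A [NoiseModel-class].
#' @return A [Chromatogram-class].
#' @export
genChromatogram <- function(fractions,
                            centres = c(16.0, 19.5, 25.0),
                            widths = rep(0.25, 3L),
                            grid = seq(10, 30, by = 0.02),
                            totalArea = 1,
                            noise = noiseModel("none")) {
    stopifnot(is(noise, "NoiseModel"), length(fractions) == 3L,
              length(centres) == 3L, length(widths) == 3L)
    validObject(noise)
    fractions <- as.numeric(fractions)
    if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
        stop("fractions must be non-negative and sum to 1", call. = FALSE)
    y <- rep(0, length(grid))
    for (k in 1:3)
        y <- y + fractions[k] * totalArea *
            exp(-(grid - centres[k])^2 / (2 * widths[k]^2)) /
            (widths[k] * sqrt(2 * pi))
    if (noise@kind != "none")
        y <- .withSeed(noise@seed,
                       .applyNoise(y, noise, rnorm(length(y))))
    Chromatogram(grid, y)
}
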