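#' @import methods
#' @importFrom stats median mad sd qnorm rnorm runif approx setNames
#' @importFrom utils read.csv write.csv packageVersion head
NULL

.SPECIES <- c("S1", "S2", "S3")

## ---------------------------------------------------------------------------
## Kinetic model containers
## ---------------------------------------------------------------------------

#' Kinetic constants of the two-step sirohaem decarboxylation model
#'
#' Holds the five rate constants of the single-active-site cascade
#' sirohaem (S1) -> monodecarboxysirohaem (S2) -> didecarboxysirohaem (S3):
#' Michaelis constants and limiting rates for each decarboxylation step plus
#' the tight-binding inhibition constant of the product. Limiting rates are
#' stored at a reference enzyme concentration `Eref` (the assay condition at
#' which they were measured); rates scale linearly with enzyme concentration
#' relative to `Eref`.
#'
#' @slot Km1 Michaelis constant of sirohaem, uM.
#' @slot Vmax1 Limiting rate of the first decarboxylation, uM/min at `Eref`.
#' @slot Km2 Michaelis constant of monodecarboxysirohaem, uM.
#' @slot Vmax2 Limiting rate of the second decarboxylation, uM/min at `Eref`.
#' @slot Ki Tight-binding inhibition constant of didecarboxysirohaem, uM.
#' @slot Eref Enzyme concentration at which the Vmax values apply, uM.
#'
#' @seealso [RateParameters()], [ddAhbABParams()]
#' @exportClass RateParameters
setClass("RateParameters",
    representation(Km1 = "numeric", Vmax1 = "numeric", Km2 = "numeric",
                   Vmax2 = "numeric", Ki = "numeric", Eref = "numeric"),
    validity = function(object) {
        vals <- c(Km1 = object@Km1, Vmax1 = object@Vmax1, Km2 = object@Km2,
                  Vmax2 = object@Vmax2, Ki = object@Ki, Eref = object@Eref)
        if (length(vals) != 6L || anyNA(vals))
            return("all six constants must be non-missing scalars")
        if (!all(is.finite(vals)) || !all(vals > 0))
            return(paste0("all constants must be strictly positive and finite; ",
                          "offending: ",
                          paste(names(vals)[!(is.finite(vals) & vals > 0)],
                                collapse = ", ")))
        TRUE
    })

#' Construct a RateParameters object
#'
#' @param Km1,Vmax1,Km2,Vmax2,Ki Kinetic constants (uM and uM/min); all must
#'   be strictly positive and finite.
#' @param Eref Reference enzyme concentration, uM (default 2.3, the progress
#'   curve assay condition).
#' @return A [RateParameters-class] object.
#' @examples
#' RateParameters(Km1 = 11.74, Vmax1 = 44.63, Km2 = 9.94,
#'                Vmax2 = 33.22, Ki = 1.77)
#' @export
RateParameters <- function(Km1, Vmax1, Km2, Vmax2, Ki, Eref = 2.3) {
    new("RateParameters", Km1 = as.numeric(Km1), Vmax1 = as.numeric(Vmax1),
        Km2 = as.numeric(Km2), Vmax2 = as.numeric(Vmax2), Ki = as.numeric(Ki),
        Eref = as.numeric(Eref))
}

#' Published kinetic parameter set for D. desulfuricans AhbA/B
#'
#' The five fitted constants of the sirohaem decarboxylase progress-curve
#' model for the Desulfovibrio desulfuricans enzyme, at the 2.3 uM enzyme
#' assay condition: Km1 = 11.74 uM, Vmax1 = 44.63 uM/min, Km2 = 9.94 uM,
#' Vmax2 = 33.22 uM/min, Ki = 1.77 uM.
#'
#' @return A [RateParameters-class] object.
#' @export
ddAhbABParams <- function() {
    RateParameters(Km1 = 11.74, Vmax1 = 44.63, Km2 = 9.94, Vmax2 = 33.22,
                   Ki = 1.77, Eref = 2.3)
}

#' Three-species progress curve of a decarboxylation assay
#'
#' Concentrations of sirohaem (S1), monodecarboxysirohaem (S2) and
#' didecarboxysirohaem (S3) on a common time grid, as simulated from the
#' kinetic model or quantified from a stopped anaerobic assay.
#'
#' @slot times Sampling times in minutes; strictly increasing, first entry 0.
#' @slot states Numeric matrix, one row per time, columns S1/S2/S3, uM.
#' @slot enzymeConc Enzyme concentration of the assay, uM (may be NA).
#' @slot replicateId Free-text replicate label (may be NA).
#'
#' @exportClass TimeCourse
setClass("TimeCourse",
    representation(times = "numeric", states = "matrix",
                   enzymeConc = "numeric", replicateId = "character"),
    validity = function(object) {
        n <- length(object@times)
        if (n < 1L) return("at least one time point required")
        if (object@times[1L] != 0) return("first time point must be 0 min")
        if (n > 1L && any(diff(object@times) <= 0))
            return("times must be strictly increasing")
        if (!is.numeric(object@states) || nrow(object@states) != n ||
            ncol(object@states) != 3L)
            return("states must be a numeric matrix with one row per time and 3 columns")
        if (anyNA(object@states) || any(object@states < 0))
            return("concentrations must be non-negative and non-missing")
        TRUE
    })

#' Construct a TimeCourse object
#'
#' @param times Sampling times, minutes; strictly increasing from 0.
#' @param states Matrix (or data.frame) of concentrations with columns
#'   S1, S2, S3 in uM; one row per time point.
#' @param enzymeConc Enzyme concentration of the assay, uM; `NA` if unknown.
#' @param replicateId Optional replicate label.
#' @return A [TimeCourse-class] object.
#' @export
TimeCourse <- function(times, states, enzymeConc = NA_real_,
                       replicateId = NA_character_) {
    states <- as.matrix(states)
    storage.mode(states) <- "double"
    dimnames(states) <- list(NULL, .SPECIES)
    new("TimeCourse", times = as.numeric(times), states = states,
        enzymeConc = as.numeric(enzymeConc),
        replicateId = as.character(replicateId))
}

#' Result of a progress-curve parameter fit
#'
#' @slot estimates Fitted [RateParameters-class].
#' @slot stdErrors Named per-parameter standard errors (same units as the
#'   estimates), or NA when not computed.
#' @slot rss Residual sum of squares, uM^2.
#' @slot residuals Per-observation residuals (observed - fitted), uM.
#' @slot converged Logical convergence flag.
#' @slot nObs Number of fitted observations.
#' @slot covariance 5x5 covariance matrix of the estimates, parameter units.
#' @slot startObjective Residual sum of squares at the selected starting
#'   point, for the objective-improvement guarantee.
#' @slot message Optimizer diagnostic message.
#'
#' @exportClass KineticFit
setClass("KineticFit",
    representation(estimates = "RateParameters", stdErrors = "numeric",
                   rss = "numeric", residuals = "numeric",
                   converged = "logical", nObs = "integer",
                   covariance = "matrix", startObjective = "numeric",
                   message = "character"),
    validity = function(object) {
        se <- object@stdErrors
        if (length(se) && any(!is.na(se) & se < 0))
            return("standard errors must be non-negative")
        if (object@rss < 0) return("residual sum of squares must be >= 0")
        TRUE
    })

## ---------------------------------------------------------------------------
## Redox titration containers
## ---------------------------------------------------------------------------

#' Absorbance-versus-potential redox titration curve
#'
#' @slot potentials Applied potentials, mV vs the normal hydrogen electrode.
#' @slot absorbances Absorbance (AU) at `wavelength` for each potential.
#' @slot wavelength Observation wavelength, nm.
#'
#' @exportClass TitrationCurve
setClass("TitrationCurve",
    representation(potentials = "numeric", absorbances = "numeric",
                   wavelength = "numeric"),
    validity = function(object) {
        if (length(object@potentials) < 5L)
            return("at least 5 titration points required")
        if (length(object@potentials) != length(object@absorbances))
            return("potentials and absorbances must have equal length")
        if (anyDuplicated(object@potentials))
            return("potentials must be distinct")
        TRUE
    })

#' Construct a TitrationCurve object
#'
#' @param potentials Applied potentials, mV vs NHE; need not be sorted but
#'   must be distinct, at least 5 values.
#' @param absorbances Absorbance in AU at each potential.
#' @param wavelength Observation wavelength, nm (default 529, the haem
#'   Q-band used for the titration).
#' @return A [TitrationCurve-class] object.
#' @export
TitrationCurve <- function(potentials, absorbances, wavelength = 529) {
    new("TitrationCurve", potentials = as.numeric(potentials),
        absorbances = as.numeric(absorbances),
        wavelength = as.numeric(wavelength))
}

#' One-electron Nernst model fit of a redox titration
#'
#' @slot Em Midpoint potential, mV vs NHE.
#' @slot nElectrons Number of electrons of the couple (fixed during fitting).
#' @slot Aox Asymptotic absorbance of the fully oxidized form, AU.
#' @slot Ared Asymptotic absorbance of the fully reduced form, AU.
#' @slot temperature Temperature, K.
#' @slot stdErrors Named standard errors for Em, Aox, Ared.
#' @slot rss Residual sum of squares, AU^2.
#' @slot residuals Per-point residuals, AU.
#' @slot converged Logical convergence flag.
#'
#' @exportClass NernstFit
setClass("NernstFit",
    representation(Em = "numeric", nElectrons = "integer", Aox = "numeric",
                   Ared = "numeric", temperature = "numeric",
                   stdErrors = "numeric", rss = "numeric",
                   residuals = "numeric", converged = "logical"),
    validity = function(object) {
        if (object@nElectrons < 1L) return("nElectrons must be >= 1")
        if (object@temperature <= 0) return("temperature must be positive, K")
        if (isTRUE(object@Aox == object@Ared))
            return("Aox and Ared must differ")
        TRUE
    })

#' Construct a NernstFit object
#'
#' Mostly used internally by [fitNernst()]; exposed so a model curve can be
#' evaluated at chosen parameters via [nernstAbsorbance()].
#'
#' @param Em Midpoint potential, mV vs NHE.
#' @param Aox,Ared Asymptotic absorbances of the oxidized / reduced forms, AU.
#' @param nElectrons Electrons transferred (default 1, Fe3+/Fe2+ couple).
#' @param temperature Temperature in K (default 298.15).
#' @param stdErrors,rss,residuals,converged Fit diagnostics; defaults mark an
#'   unfitted parameter set.
#' @return A [NernstFit-class] object.
#' @export
NernstFit <- function(Em, Aox, Ared, nElectrons = 1L, temperature = 298.15,
                      stdErrors = c(Em = NA_real_, Aox = NA_real_,
                                    Ared = NA_real_),
                      rss = NA_real_, residuals = numeric(0),
                      converged = NA) {
    new("NernstFit", Em = as.numeric(Em), nElectrons = as.integer(nElectrons),
        Aox = as.numeric(Aox), Ared = as.numeric(Ared),
        temperature = as.numeric(temperature), stdErrors = stdErrors,
        rss = rss, residuals = residuals, converged = as.logical(converged))
}

## ---------------------------------------------------------------------------
## Spectroscopy containers
## ---------------------------------------------------------------------------

#' UV-visible absorbance spectrum
#'
#' @slot wavelengths Wavelengths, nm, strictly increasing.
#' @slot absorbances Absorbance, AU, one value per wavelength.
#' @slot label Free-text label (e.g. "oxidized", "reduced").
#'
#' @exportClass Spectrum
setClass("Spectrum",
    representation(wavelengths = "numeric", absorbances = "numeric",
                   label = "character"),
    validity = function(object) {
        if (length(object@wavelengths) != length(object@absorbances))
            return("wavelengths and absorbances must have equal length")
        if (length(object@wavelengths) > 1L &&
            any(diff(object@wavelengths) <= 0))
            return("wavelengths must be strictly increasing")
        TRUE
    })

#' Construct a Spectrum object
#'
#' @param wavelengths Wavelengths, nm, strictly increasing.
#' @param absorbances Absorbance, AU.
#' @param label Free-text label.
#' @return A [Spectrum-class] object.
#' @export
Spectrum <- function(wavelengths, absorbances, label = NA_character_) {
    new("Spectrum", wavelengths = as.numeric(wavelengths),
        absorbances = as.numeric(absorbances), label = as.character(label))
}

#' Reduced-minus-oxidized difference spectrum
#'
#' A [Spectrum-class] with provenance recording which reduced and oxidized
#' spectra it was computed from. Only spectra on identical wavelength grids
#' may be differenced (no silent interpolation).
#'
#' @slot provenance Character vector of length 2: (reduced label,
#'   oxidized label).
#'
#' @exportClass DifferenceSpectrum
setClass("DifferenceSpectrum", contains = "Spectrum",
    representation(provenance = "character"),
    validity = function(object) {
        if (length(object@provenance) != 2L)
            return("provenance must name the reduced and oxidized spectra")
        TRUE
    })

#' HPLC chromatogram trace
#'
#' Retention-time / signal pairs as recorded at 380 nm.
#'
#' @slot retentionTimes Retention times, minutes, strictly increasing,
#'   non-negative.
#' @slot signal Detector signal, AU.
#'
#' @exportClass Chromatogram
setClass("Chromatogram",
    representation(retentionTimes = "numeric", signal = "numeric"),
    validity = function(object) {
        if (length(object@retentionTimes) != length(object@signal))
            return("retentionTimes and signal must have equal length")
        if (length(object@retentionTimes) &&
            (any(object@retentionTimes < 0)))
            return("retention times must be non-negative")
        if (length(object@retentionTimes) > 1L &&
            any(diff(object@retentionTimes) <= 0))
            return("retention times must be strictly increasing")
        TRUE
    })

#' Construct a Chromatogram object
#'
#' @param retentionTimes Retention times, minutes, strictly increasing.
#' @param signal Detector signal at 380 nm, AU.
#' @return A [Chromatogram-class] object.
#' @export
Chromatogram <- function(retentionTimes, signal) {
    new("Chromatogram", retentionTimes = as.numeric(retentionTimes),
        signal = as.numeric(signal))
}

## ---------------------------------------------------------------------------
## Noise model for the synthetic-data generators
## ---------------------------------------------------------------------------

#' Observation-noise model for synthetic data
#'
#' @slot kind One of "none", "multiplicative_gaussian", "additive_gaussian".
#' @slot cvOrSd Coefficient of variation (fraction, multiplicative) or
#'   standard deviation (AU/uM, additive).
#' @slot floor Value below which noisy observations are clipped to 0.
#' @slot seed RNG seed; mandatory unless kind is "none".
#'
#' @exportClass NoiseModel
setClass("NoiseModel",
    representation(kind = "character", cvOrSd = "numeric", floor = "numeric",
                   seed = "integer"),
    validity = function(object) {
        kinds <- c("none", "multiplicative_gaussian", "additive_gaussian")
        if (!object@kind %in% kinds)
            return(paste("kind must be one of:", paste(kinds, collapse = ", ")))
        if (is.na(object@cvOrSd) || object@cvOrSd < 0)
            return("cvOrSd must be >= 0")
        if (object@kind != "none" && is.na(object@seed))
            return("seed is mandatory when noise is applied")
        TRUE
    })

#' Construct a NoiseModel
#'
#' @param kind "none", "multiplicative_gaussian" (value x (1 + cv x z)) or
#'   "additive_gaussian" (value + sd x z), z ~ N(0, 1) independently per
#'   observation.
#' @param cvOrSd Coefficient of variation (fraction) for multiplicative
#'   noise, standard deviation (data units) for additive noise.
#' @param floor Clip noisy values below this to 0 (default 0, i.e. enforce
#'   non-negativity).
#' @param seed Integer RNG seed; required unless `kind = "none"`.
#' @return A [NoiseModel-class] object.
#' @examples
#' noiseModel("multiplicative_gaussian", 0.05, seed = 1)
#' @export
noiseModel <- function(kind = c("none", "multiplicative_gaussian",
                                "additive_gaussian"),
                       cvOrSd = 0, floor = 0, seed = NA_integer_) {
    kind <- match.arg(kind)
    new("NoiseModel", kind = kind, cvOrSd = as.numeric(cvOrSd),
        floor = as.numeric(floor), seed = as.integer(seed))
}
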