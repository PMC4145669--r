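## Accessor generics and show methods. Slot access from user code is
## discouraged; these accessors are the supported surface.

#' Sampling times of a time course
#' @param x A [TimeCourse-class].
#' @return Numeric vector of times, minutes.
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname timePoints
#' @export
setMethod("timePoints", "TimeCourse", function(x) x@times)

#' Concentration matrix of a time course
#' @param x A [TimeCourse-class].
#' @return Numeric matrix, one row per time, columns S1/S2/S3, uM.
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname concentrations
#' @export
setMethod("concentrations", "TimeCourse", function(x) x@states)

#' Enzyme concentration of an assay time course
#' @param x A [TimeCourse-class].
#' @return Enzyme concentration, uM (NA if unrecorded).
#' @export
setGeneric("enzymeConc", function(x) standardGeneric("enzymeConc"))

#' @rdname enzymeConc
#' @export
setMethod("enzymeConc", "TimeCourse", function(x) x@enzymeConc)

#' Fitted kinetic parameters
#' @param object A [KineticFit-class].
#' @return For `estimates`, the fitted [RateParameters-class]; for
#'   `stdErrors`, the named per-parameter standard errors.
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))

#' @rdname estimates
#' @export
setMethod("estimates", "KineticFit", function(object) object@estimates)

#' @rdname estimates
#' @export
setGeneric("stdErrors", function(object) standardGeneric("stdErrors"))

#' @rdname estimates
#' @export
setMethod("stdErrors", "KineticFit", function(object) object@stdErrors)

#' @rdname estimates
#' @export
setMethod("stdErrors", "NernstFit", function(object) object@stdErrors)

#' Convergence flag of a fit
#' @param object A [KineticFit-class] or [NernstFit-class].
#' @return Logical.
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname converged
#' @export
setMethod("converged", "KineticFit", function(object) object@converged)

#' @rdname converged
#' @export
setMethod("converged", "NernstFit", function(object) object@converged)

#' Midpoint potential of a Nernst fit
#' @param object A [NernstFit-class].
#' @return Midpoint potential, mV vs NHE.
#' @export
setGeneric("midpointPotential",
           function(object) standardGeneric("midpointPotential"))

#' @rdname midpointPotential
#' @export
setMethod("midpointPotential", "NernstFit", function(object) object@Em)

#' Wavelength grid of a spectrum
#' @param x A [Spectrum-class].
#' @return Numeric vector, nm.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "Spectrum", function(x) x@wavelengths)

#' Absorbance values of a spectrum
#' @param x A [Spectrum-class].
#' @return Numeric vector, AU.
#' @export
setGeneric("absorbances", function(x) standardGeneric("absorbances"))

#' @rdname absorbances
#' @export
setMethod("absorbances", "Spectrum", function(x) x@absorbances)

#' Kinetic constants as a named vector
#' @param object A [RateParameters-class].
#' @return Named numeric vector (Km1, Vmax1, Km2, Vmax2, Ki), without Eref.
#' @export
setGeneric("paramVector", function(object) standardGeneric("paramVector"))

#' @rdname paramVector
#' @export
setMethod("paramVector", "RateParameters", function(object)
    c(Km1 = object@Km1, Vmax1 = object@Vmax1, Km2 = object@Km2,
      Vmax2 = object@Vmax2, Ki = object@Ki))

#' @describeIn TimeCourse-class Data-frame view (`time_min`, `S1_uM`,
#'   `S2_uM`, `S3_uM`).
#' @param x A [TimeCourse-class].
#' @param ... Unused.
#' @export
setMethod("as.data.frame", "TimeCourse", function(x, ...) {
    data.frame(time_min = x@times, S1_uM = x@states[, 1L],
               S2_uM = x@states[, 2L], S3_uM = x@states[, 3L],
               row.names = NULL)
})

#' @describeIn Spectrum-class Data-frame view (`wavelength_nm`, `absorbance`).
#' @param x A [Spectrum-class].
#' @param ... Unused.
#' @export
setMethod("as.data.frame", "Spectrum", function(x, ...) {
    data.frame(wavelength_nm = x@wavelengths, absorbance = x@absorbances,
               row.names = NULL)
})

#' @describeIn TitrationCurve-class Data-frame view (`potential_mV_NHE`,
#'   `absorbance`, `wavelength_nm`).
#' @param x A [TitrationCurve-class].
#' @param ... Unused.
#' @export
setMethod("as.data.frame", "TitrationCurve", function(x, ...) {
    data.frame(potential_mV_NHE = x@potentials, absorbance = x@absorbances,
               wavelength_nm = x@wavelength, row.names = NULL)
})

#' @describeIn Chromatogram-class Data-frame view (`time_min`, `signal`).
#' @param x A [Chromatogram-class].
#' @param ... Unused.
#' @export
setMethod("as.data.frame", "Chromatogram", function(x, ...) {
    data.frame(time_min = x@retentionTimes, signal = x@signal,
               row.names = NULL)
})

setMethod("show", "RateParameters", function(object) {
    cat("RateParameters (two-step decarboxylation, competitive/tight-binding)\n")
    cat(sprintf("  Km1 = %.4g uM, Vmax1 = %.4g uM/min\n", object@Km1,
                object@Vmax1))
    cat(sprintf("  Km2 = %.4g uM, Vmax2 = %.4g uM/min\n", object@Km2,
                object@Vmax2))
    cat(sprintf("  Ki  = %.4g uM (product tight binding)\n", object@Ki))
    cat(sprintf("  Vmax reference enzyme concentration: %.4g uM\n",
                object@Eref))
    invisible(NULL)
})

setMethod("show", "TimeCourse", function(object) {
    cat(sprintf("TimeCourse: %d time points over %.4g-%.4g min\n",
                length(object@times), min(object@times), max(object@times)))
    if (!is.na(object@enzymeConc))
        cat(sprintf("  enzyme: %.4g uM\n", object@enzymeConc))
    if (!is.na(object@replicateId))
        cat(sprintf("  replicate: %s\n", object@replicateId))
    tot <- rowSums(object@states)
    cat(sprintf("  total tetrapyrrole: %.6g-%.6g uM\n", min(tot), max(tot)))
    invisible(NULL)
})

setMethod("show", "KineticFit", function(object) {
    cat(sprintf("KineticFit: %s (%d observations, RSS = %.6g uM^2)\n",
                if (isTRUE(object@converged)) "converged" else "NOT converged",
                object@nObs, object@rss))
    est <- paramVector(object@estimates)
    se <- object@stdErrors[names(est)]
    for (p in names(est))
        cat(sprintf("  %-6s = %10.5g +/- %-10.4g\n", p, est[[p]], se[[p]]))
    if (nzchar(object@message)) cat("  ", object@message, "\n", sep = "")
    invisible(NULL)
})

setMethod("show", "NernstFit", function(object) {
    cat(sprintf("NernstFit (n = %d, T = %.2f K): Em = %.2f mV vs NHE",
                object@nElectrons, object@temperature, object@Em))
    if (!is.na(object@stdErrors[["Em"]]))
        cat(sprintf(" +/- %.2f", object@stdErrors[["Em"]]))
    cat("\n")
    cat(sprintf("  Aox = %.4g AU, Ared = %.4g AU\n", object@Aox, object@Ared))
    invisible(NULL)
})

setMethod("show", "Spectrum", function(object) {
    cat(sprintf("%s: %d points, %.4g-%.4g nm%s\n", class(object),
                length(object@wavelengths), min(object@wavelengths),
                max(object@wavelengths),
                if (!is.na(object@label)) paste0(" [", object@label, "]")
                else ""))
    invisible(NULL)
})

setMethod("show", "Chromatogram", function(object) {
    cat(sprintf("Chromatogram: %d points, %.4g-%.4g min\n",
                length(object@retentionTimes), min(object@retentionTimes),
                max(object@retentionTimes)))
    invisible(NULL)
})
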