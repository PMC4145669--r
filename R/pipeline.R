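## Pipeline driver tying the stages together. Each subcommand consumes and
## produces the CSV formats of the io module, so stages can be chained
## (synthesize -> fit, synthesize -> titrate, ...). A thin command-line
## wrapper over this function ships at inst/cli/sirodecarb.R.

.logInfo <- function(verbose, fmt, ...) {
    if (verbose) message(sprintf(paste0("[sirodecarb] ", fmt), ...))
    invisible(NULL)
}

.parseTimesSpec <- function(spec) {
    if (is.null(spec) || !nzchar(spec)) return(defaultKineticTimes())
    as.numeric(strsplit(spec, ",", fixed = TRUE)[[1L]])
}

#' Run one stage of the analysis pipeline
#'
#' Drives the package's stages from a single configuration, mirroring the
#' shipped command-line wrapper. Subcommands:
#' \describe{
#'   \item{simulate}{`params` (config file), `s0`, `enzyme`, `times`
#'     (comma-separated minutes) -> progress-curve CSV at `output`.}
#'   \item{fit}{`input` (progress-curve CSV), `params` (initial-guess
#'     config) -> fit report at `output` (+ `residualOutput`).}
#'   \item{titrate}{`input` (titration CSV) -> one-line Em report at
#'     `output`; returns the [NernstFit-class].}
#'   \item{haemochrome}{`input` (reduced CSV), `input2` (oxidized CSV) ->
#'     alpha/beta apex and haem class report at `output`.}
#'   \item{hplc-assign}{`input` (chromatogram CSV) -> peak-assignment CSV
#'     at `output`.}
#'   \item{synth}{`scenario` in `kinetics`, `titration`, `haemochrome-b`,
#'     `hplc-trace`; writes the scenario's CSV(s) under `output` (a
#'     directory), using `seed` for the noise draws (0 or NA = noiseless).}
#' }
#'
#' @param subcommand One of the stage names above.
#' @param input,input2 Input file paths (stage-dependent).
#' @param output Output file (or directory, for `synth`).
#' @param residualOutput Optional residual CSV path for `fit`.
#' @param params Parameter/configuration file path.
#' @param scenario Scenario name for `synth`.
#' @param s0 Initial sirohaem concentration, uM (simulate/synth;
#'   default 23).
#' @param enzyme Enzyme concentration, uM (default 2.3).
#' @param times Comma-separated sampling times, minutes (default the
#'   geometric 0-120 min grid).
#' @param tolerance Retention-time matching tolerance, min (hplc-assign).
#' @param nElectrons,temperature Nernst settings (titrate).
#' @param seed Seed recorded in outputs and used for any noise.
#' @param verbose Log each stage at INFO level (default TRUE).
#' @return The stage's principal result object, invisibly.
#' @export
runPipeline <- function(subcommand = c("simulate", "fit", "titrate",
                                       "haemochrome", "hplc-assign",
                                       "synth"),
                        input = NULL, input2 = NULL, output = NULL,
                        residualOutput = NULL, params = NULL,
                        scenario = NULL, s0 = 23, enzyme = 2.3,
                        times = NULL, tolerance = 1.0, nElectrons = 1L,
                        temperature = 298.15, seed = 1L, verbose = TRUE) {
    subcommand <- match.arg(subcommand)
    .logInfo(verbose, "stage %s (seed %s)", subcommand, as.character(seed))

    if (subcommand == "simulate") {
        p <- readRateParams(params)
        tc <- simulateTimeCourse(p, c(s0, 0, 0), .parseTimesSpec(times),
                                 enzymeConc = enzyme)
        writeTimeCourse(tc, output)
        .logInfo(verbose, "wrote %s (%d time points)", output,
                 length(timePoints(tc)))
        return(invisible(tc))
    }
    if (subcommand == "fit") {
        data <- readTimeCourse(input, enzymeConc = enzyme)
        guess <- readRateParams(params)
        fit <- fitTimeCourse(data, guess, seed = seed)
        writeFitReport(fit, output, residualPath = residualOutput,
                       seed = seed)
        .logInfo(verbose, "fit %s: RSS %.6g uM^2, wrote %s",
                 if (isTRUE(converged(fit))) "converged" else "NOT converged",
                 fit@rss, output)
        return(invisible(fit))
    }
    if (subcommand == "titrate") {
        curve <- readTitration(input)
        fit <- fitNernst(curve, nElectrons = nElectrons,
                         temperature = temperature)
        if (!is.null(output))
            writeLines(c(.provenanceHeader(
                c(sprintf("# n_electrons: %d", fit@nElectrons),
                  sprintf("# temperature_K: %.15g", fit@temperature))),
                "Em_mV_NHE,stderr_mV,Aox_AU,Ared_AU",
                sprintf("%.6f,%.6f,%.8g,%.8g", fit@Em,
                        fit@stdErrors[["Em"]], fit@Aox, fit@Ared)),
                output)
        .logInfo(verbose, "Em = %.2f +/- %.2f mV vs NHE", fit@Em,
                 fit@stdErrors[["Em"]])
        return(invisible(fit))
    }
    if (subcommand == "haemochrome") {
        red <- readSpectrum(input, label = "reduced")
        ox <- readSpectrum(input2, label = "oxidized")
        d <- differenceSpectrum(red, ox)
        alpha <- findAlphaPeak(d)
        beta <- tryCatch(findAlphaPeak(d, window = c(522, 535)),
                         error = function(e) NA_real_)
        klass <- classifyHaem(as.numeric(alpha))
        if (!is.null(output))
            writeLines(c(.provenanceHeader(),
                "alpha_peak_nm,beta_peak_nm,haem_class",
                sprintf("%.3f,%s,%s", as.numeric(alpha),
                        if (is.na(beta)) "NA" else
                            sprintf("%.3f", as.numeric(beta)), klass)),
                output)
        .logInfo(verbose, "alpha apex %.2f nm -> %s", as.numeric(alpha),
                 klass)
        return(invisible(list(alpha = alpha, beta = beta, class = klass,
                              difference = d)))
    }
    if (subcommand == "hplc-assign") {
        chrom <- readChromatogram(input)
        asg <- assignHplcPeaks(chrom, tolerance = tolerance)
        if (!is.null(output)) .writeTable(asg, output)
        .logInfo(verbose, "%d peak(s) detected", nrow(asg))
        return(invisible(asg))
    }
    ## synth
    if (is.null(scenario))
        stop("synth requires a scenario", call. = FALSE)
    if (!dir.exists(output)) dir.create(output, recursive = TRUE)
    noisy <- !is.na(seed) && seed > 0
    res <- switch(scenario,
        "kinetics" = {
            reps <- genTimeCourse(ddAhbABParams(), c(s0, 0, 0),
                                  enzymeConc = enzyme,
                                  nReplicates = if (noisy) 3L else 1L,
                                  noise = if (noisy)
                                      noiseModel("multiplicative_gaussian",
                                                 0.05, seed = seed)
                                  else noiseModel("none"))
            writeTimeCourse(reps, file.path(output, "timecourse.csv"))
            writeRateParams(ddAhbABParams(),
                            file.path(output, "params_true.cfg"))
            reps
        },
        "titration" = {
            curve <- genTitration(Em = -98, Aox = 0.1, Ared = 0.35,
                                  noise = if (noisy)
                                      noiseModel("additive_gaussian",
                                                 0.005, seed = seed)
                                  else noiseModel("none"))
            .writeTable(as.data.frame(curve),
                        file.path(output, "titration.csv"))
            curve
        },
        "haemochrome-b" = {
            pair <- genHaemochromePair(556,
                noise = if (noisy)
                    noiseModel("additive_gaussian", 0.001, seed = seed)
                else noiseModel("none"))
            .writeTable(as.data.frame(pair$reduced),
                        file.path(output, "reduced.csv"))
            .writeTable(as.data.frame(pair$oxidized),
                        file.path(output, "oxidized.csv"))
            pair
        },
        "hplc-trace" = {
            chrom <- genChromatogram(c(0.2, 0.3, 0.5),
                noise = if (noisy)
                    noiseModel("additive_gaussian", 0.002, seed = seed)
                else noiseModel("none"))
            .writeTable(as.data.frame(chrom),
                        file.path(output, "chromatogram.csv"))
            chrom
        },
        stop("unknown scenario: ", scenario, call. = FALSE))
    .logInfo(verbose, "scenario %s written under %s", scenario, output)
    invisible(res)
}
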