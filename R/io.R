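## CSV readers/writers for the assay table formats. Units are encoded in
## the column names (`_uM`, `_min`, `_mV_NHE`, `_nm`) so unit errors are
## loud; schema violations are reported with the offending row/column.
## Decimal point and UTF-8 throughout, independent of locale.

.readTable <- function(path, required) {
    if (!file.exists(path))
        stop("input file not found: ", path, call. = FALSE)
    df <- read.csv(path, comment.char = "#", fileEncoding = "UTF-8")
    missing <- setdiff(required, names(df))
    if (length(missing))
        stop(sprintf("%s: missing required column(s): %s", path,
                     paste(missing, collapse = ", ")), call. = FALSE)
    for (col in required) {
        if (!is.numeric(df[[col]])) {
            bad <- which(is.na(suppressWarnings(
                as.numeric(as.character(df[[col]])))))[1L]
            stop(sprintf("%s: non-numeric value in column '%s' (row %d)",
                         path, col, if (is.na(bad)) 1L else bad),
                 call. = FALSE)
        }
        if (anyNA(df[[col]]))
            stop(sprintf("%s: missing value in column '%s' (row %d)", path,
                         col, which(is.na(df[[col]]))[1L]), call. = FALSE)
    }
    df
}

.provenanceHeader <- function(extra = character(0)) {
    c(sprintf("# sirodecarb %s", as.character(packageVersion("sirodecarb"))),
      sprintf("# written %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      extra)
}

.writeTable <- function(df, path, extra = character(0)) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(.provenanceHeader(extra), con)
    write.csv(df, con, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a progress-curve CSV
#'
#' Expects columns `time_min,S1_uM,S2_uM,S3_uM` and optionally `replicate`.
#' Lines starting `#` are provenance comments. With a replicate column a
#' list of per-replicate [TimeCourse-class] objects is returned, otherwise
#' a single one.
#'
#' @param path CSV file path.
#' @param enzymeConc Enzyme concentration to attach, uM (optional).
#' @return A [TimeCourse-class], or a named list of them.
#' @export
readTimeCourse <- function(path, enzymeConc = NA_real_) {
    df <- .readTable(path, c("time_min", "S1_uM", "S2_uM", "S3_uM"))
    conc <- as.matrix(df[, c("S1_uM", "S2_uM", "S3_uM")])
    if (any(conc < 0)) {
        bad <- which(conc < 0, arr.ind = TRUE)[1L, ]
        stop(sprintf(
            "%s: negative concentration in column '%s' (row %d)", path,
            c("S1_uM", "S2_uM", "S3_uM")[bad[["col"]]], bad[["row"]]),
            call. = FALSE)
    }
    makeOne <- function(sub, id) {
        if (nrow(sub) > 1L && any(diff(sub$time_min) <= 0))
            stop(sprintf("%s: time_min not strictly increasing (row %d)",
                         path, which(diff(sub$time_min) <= 0)[1L] + 1L),
                 call. = FALSE)
        TimeCourse(sub$time_min,
                   as.matrix(sub[, c("S1_uM", "S2_uM", "S3_uM")]),
                   enzymeConc = enzymeConc, replicateId = id)
    }
    if ("replicate" %in% names(df)) {
        ids <- unique(df$replicate)
        out <- lapply(ids, function(id)
            makeOne(df[df$replicate == id, , drop = FALSE],
                    as.character(id)))
        names(out) <- as.character(ids)
        out
    } else makeOne(df, NA_character_)
}

#' Write progress-curve data to CSV
#'
#' @param tc A [TimeCourse-class] or a list of replicates.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeTimeCourse <- function(tc, path) {
    if (is(tc, "TimeCourse")) tc <- list(tc)
    dfs <- lapply(tc, function(x) {
        df <- as.data.frame(x)
        if (!is.na(x@replicateId)) df$replicate <- x@replicateId
        df
    })
    .writeTable(do.call(rbind, dfs), path)
}

#' Read a kinetic parameter configuration
#'
#' A flat key-value file (`key = value` per line, `#` comments) with keys
#' `Km1_uM, Vmax1_uM_per_min, Km2_uM, Vmax2_uM_per_min, Ki_uM, E_ref_uM`.
#'
#' @param path Configuration file path.
#' @return A [RateParameters-class].
#' @export
readRateParams <- function(path) {
    if (!file.exists(path))
        stop("parameter file not found: ", path, call. = FALSE)
    lines <- readLines(path, encoding = "UTF-8")
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "\\s*[=:]\\s*")
    bad <- which(lengths(kv) != 2L)
    if (length(bad))
        stop(sprintf("%s: cannot parse line %d ('%s')", path, bad[1L],
                     lines[bad[1L]]), call. = FALSE)
    vals <- setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                     vapply(kv, `[`, "", 1L))
    need <- c("Km1_uM", "Vmax1_uM_per_min", "Km2_uM", "Vmax2_uM_per_min",
              "Ki_uM")
    missing <- setdiff(need, names(vals))
    if (length(missing))
        stop(sprintf("%s: missing key(s): %s", path,
                     paste(missing, collapse = ", ")), call. = FALSE)
    RateParameters(Km1 = vals[["Km1_uM"]], Vmax1 = vals[["Vmax1_uM_per_min"]],
                   Km2 = vals[["Km2_uM"]], Vmax2 = vals[["Vmax2_uM_per_min"]],
                   Ki = vals[["Ki_uM"]],
                   Eref = if ("E_ref_uM" %in% names(vals))
                       vals[["E_ref_uM"]] else 2.3)
}

#' Write a kinetic parameter configuration
#'
#' @param params A [RateParameters-class].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeRateParams <- function(params, path) {
    stopifnot(is(params, "RateParameters"))
    writeLines(c(.provenanceHeader(),
                 sprintf("Km1_uM = %.15g", params@Km1),
                 sprintf("Vmax1_uM_per_min = %.15g", params@Vmax1),
                 sprintf("Km2_uM = %.15g", params@Km2),
                 sprintf("Vmax2_uM_per_min = %.15g", params@Vmax2),
                 sprintf("Ki_uM = %.15g", params@Ki),
                 sprintf("E_ref_uM = %.15g", params@Eref)),
               path, useBytes = FALSE)
    invisible(path)
}

#' Read a redox titration CSV
#'
#' Expects columns `potential_mV_NHE,absorbance` and optionally
#' `wavelength_nm`.
#'
#' @param path CSV file path.
#' @return A [TitrationCurve-class].
#' @export
readTitration <- function(path) {
    df <- .readTable(path, c("potential_mV_NHE", "absorbance"))
    wl <- if ("wavelength_nm" %in% names(df)) df$wavelength_nm[1L] else
        NA_real_
    TitrationCurve(df$potential_mV_NHE, df$absorbance, wavelength = wl)
}

#' Read a spectrum CSV
#'
#' Expects columns `wavelength_nm,absorbance`.
#'
#' @param path CSV file path.
#' @param label Label to attach (e.g. "reduced").
#' @return A [Spectrum-class].
#' @export
readSpectrum <- function(path, label = NA_character_) {
    df <- .readTable(path, c("wavelength_nm", "absorbance"))
    Spectrum(df$wavelength_nm, df$absorbance, label = label)
}

#' Read an HPLC chromatogram CSV
#'
#' Expects columns `time_min,signal`.
#'
#' @param path CSV file path.
#' @return A [Chromatogram-class].
#' @export
readChromatogram <- function(path) {
    df <- .readTable(path, c("time_min", "signal"))
    Chromatogram(df$time_min, df$signal)
}

#' Write a fit report
#'
#' Writes the parameter table (`parameter,estimate,stderr,unit`) with a
#' provenance header (model form, seed, convergence state, package
#' version), and optionally a residual table.
#'
#' @param fit A [KineticFit-class].
#' @param path Output CSV path for the parameter table.
#' @param residualPath Optional output CSV path for the residuals.
#' @param seed Seed used for the fit, recorded in the header.
#' @return The report path, invisibly.
#' @export
writeFitReport <- function(fit, path, residualPath = NULL, seed = NA) {
    stopifnot(is(fit, "KineticFit"))
    est <- paramVector(fit@estimates)
    units <- c(Km1 = "uM", Vmax1 = "uM/min", Km2 = "uM", Vmax2 = "uM/min",
               Ki = "uM")
    df <- data.frame(parameter = names(est), estimate = unname(est),
                     stderr = unname(fit@stdErrors[names(est)]),
                     unit = unname(units[names(est)]))
    extra <- c("# model: two-step competitive inhibition with tight-binding product term",
               sprintf("# E_ref_uM: %.15g", fit@estimates@Eref),
               sprintf("# seed: %s", as.character(seed)),
               sprintf("# converged: %s", fit@converged),
               sprintf("# rss_uM2: %.15g", fit@rss),
               sprintf("# n_obs: %d", fit@nObs))
    .writeTable(df, path, extra)
    if (!is.null(residualPath))
        .writeTable(data.frame(index = seq_along(fit@residuals),
                               residual_uM = fit@residuals),
                    residualPath,
                    sprintf("# converged: %s", fit@converged))
    invisible(path)
}

#' Re-read a fit report parameter table
#'
#' @param path Report written by [writeFitReport()].
#' @return A data.frame (parameter, estimate, stderr, unit) with the
#'   header's convergence flag as attribute `"converged"`.
#' @export
readFitReport <- function(path) {
    df <- .readTable(path, c("estimate"))
    hdr <- grep("^#", readLines(path, encoding = "UTF-8"), value = TRUE)
    conv <- grep("^# converged:", hdr, value = TRUE)
    attr(df, "converged") <- if (length(conv))
        as.logical(trimws(sub("^# converged:", "", conv[1L]))) else NA
    df
}
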