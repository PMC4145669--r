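## Pyridine haemochrome difference spectroscopy and HPLC peak handling.
## Haem type is diagnosed from the alpha-band apex of the reduced-minus-
## oxidized pyridine haemochrome spectrum (b type ~556 nm, c type ~550 nm);
## chromatogram peaks are assigned to tetrapyrrole species by retention
## time (sirohaem ~16 min, monodecarboxysirohaem ~19.5 min,
## didecarboxysirohaem ~25 min).

.HPLC_REFERENCE <- c(SH = 16.0, MDSH = 19.5, DDSH = 25.0)

#' Reduced-minus-oxidized difference spectrum
#'
#' Point-wise subtraction of the oxidized from the reduced spectrum. The
#' two spectra must be on identical wavelength grids; mismatched grids are
#' an error, never silently interpolated.
#'
#' @param reduced,oxidized [Spectrum-class] objects on the same grid.
#' @return A [DifferenceSpectrum-class].
#' @export
differenceSpectrum <- function(reduced, oxidized) {
    stopifnot(is(reduced, "Spectrum"), is(oxidized, "Spectrum"))
    validObject(reduced); validObject(oxidized)
    if (length(reduced@wavelengths) != length(oxidized@wavelengths) ||
        any(reduced@wavelengths != oxidized@wavelengths))
        stop("spectra are on different wavelength grids; ",
             "re-measure or resample explicitly before differencing",
             call. = FALSE)
    new("DifferenceSpectrum",
        wavelengths = reduced@wavelengths,
        absorbances = reduced@absorbances - oxidized@absorbances,
        label = "reduced - oxidized",
        provenance = c(reduced = as.character(reduced@label),
                       oxidized = as.character(oxidized@label)))
}

## Vertex of the parabola through three points (Lagrange form); NA when
## the points are collinear.
.parabolicVertex <- function(x, y) {
    d21 <- x[2L] - x[1L]; d23 <- x[2L] - x[3L]
    num <- d21^2 * (y[2L] - y[3L]) - d23^2 * (y[2L] - y[1L])
    den <- d21 * (y[2L] - y[3L]) - d23 * (y[2L] - y[1L])
    if (den == 0) return(NA_real_)
    x[2L] - 0.5 * num / den
}

#' Locate the alpha-band apex of a difference spectrum
#'
#' Finds the discrete maximum inside the search window and refines the apex
#' by parabolic interpolation through the maximum and its two neighbours.
#' A signal that is monotone across the window (discrete maximum on the
#' window edge) or flat carries no interior peak and raises a no-peak
#' error.
#'
#' @param diff A [DifferenceSpectrum-class] (any [Spectrum-class] works).
#' @param window Search window in nm; default `c(540, 575)`, the
#'   haemochrome alpha-band region. Use `c(522, 535)` to report the
#'   beta band.
#' @return Apex wavelength in nm (numeric scalar), with the interpolated
#'   apex height attached as attribute `"height"`.
#' @export
findAlphaPeak <- function(diff, window = c(540, 575)) {
    stopifnot(is(diff, "Spectrum"))
    validObject(diff)
    wl <- diff@wavelengths
    if (window[1L] < min(wl) || window[2L] > max(wl))
        stop("search window extends beyond the measured spectrum",
             call. = FALSE)
    inWin <- which(wl >= window[1L] & wl <= window[2L])
    if (length(inWin) < 3L)
        stop("need at least 3 points inside the search window",
             call. = FALSE)
    y <- diff@absorbances[inWin]
    x <- wl[inWin]
    i <- which.max(y)
    if (i == 1L || i == length(y) || all(y == y[1L]))
        stop("no interior maximum in the search window: ",
             "signal is flat or monotone (no alpha band detected)",
             call. = FALSE)
    idx <- (i - 1L):(i + 1L)
    apex <- .parabolicVertex(x[idx], y[idx])
    if (is.na(apex))
        stop("no interior maximum in the search window (collinear points)",
             call. = FALSE)
    apex <- min(max(apex, window[1L]), window[2L])
    co <- stats::lm.fit(cbind(1, x[idx] - apex, (x[idx] - apex)^2), y[idx])
    attr(apex, "height") <- unname(co$coefficients[1L])
    apex
}

#' Classify haem type from the haemochrome alpha-band apex
#'
#' Pyridine haemochrome alpha maxima near 556 nm indicate b-type haem and
#' near 550 nm c-type haem; apices between the two class boundaries are
#' reported as intermediate (e.g. shifted spectra of tightly protein-bound
#' haem). Default boundaries: >= 555 nm is haem_b, <= 551 nm is haem_c.
#'
#' @param peak Alpha apex wavelength, nm; must lie in `window`.
#' @param bBoundary Minimum wavelength classified haem_b (default 555).
#' @param cBoundary Maximum wavelength classified haem_c (default 551).
#' @param window Admissible apex range (default `c(540, 575)`); values
#'   outside it are refused.
#' @return One of "haem_b", "haem_c", "intermediate".
#' @examples
#' classifyHaem(556)  # haem_b
#' classifyHaem(554)  # intermediate
#' classifyHaem(550)  # haem_c
#' @export
classifyHaem <- function(peak, bBoundary = 555, cBoundary = 551,
                         window = c(540, 575)) {
    peak <- as.numeric(peak)
    stopifnot(length(peak) == 1L, !is.na(peak), cBoundary < bBoundary)
    if (peak < window[1L] || peak > window[2L])
        stop(sprintf(
            "apex %.1f nm lies outside the admissible window [%g, %g] nm; classification refused",
            peak, window[1L], window[2L]), call. = FALSE)
    if (peak >= bBoundary) "haem_b"
    else if (peak <= cBoundary) "haem_c"
    else "intermediate"
}

.trapz <- function(x, y)
    sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)

#' Assign HPLC chromatogram peaks to tetrapyrrole species
#'
#' Detects local maxima rising above a noise-derived threshold (5 x the
#' median absolute deviation of the first two minutes of baseline, above
#' the baseline median) and matches each to the nearest reference retention
#' time — sirohaem 16.0 min, monodecarboxysirohaem 19.5 min,
#' didecarboxysirohaem 25.0 min — within `tolerance`. Peaks with no
#' reference inside the tolerance are labelled "unassigned". Areas are
#' trapezoidal integrals between the flanking minima of each peak.
#'
#' @param chrom A [Chromatogram-class].
#' @param tolerance Maximum |observed - reference| retention difference for
#'   assignment, minutes (default 1.0).
#' @param reference Named reference retention times, minutes.
#' @return A data.frame with columns `species` ("SH", "MDSH", "DDSH" or
#'   "unassigned"), `retention_time` (min), `area` (AU min) and
#'   `apex_height` (AU), ordered by retention time; zero rows when no peak
#'   is detected.
#' @export
assignHplcPeaks <- function(chrom, tolerance = 1.0,
                            reference = c(SH = 16.0, MDSH = 19.5,
                                          DDSH = 25.0)) {
    stopifnot(is(chrom, "Chromatogram"))
    validObject(chrom)
    empty <- data.frame(species = character(0), retention_time = numeric(0),
                        area = numeric(0), apex_height = numeric(0))
    t <- chrom@retentionTimes
    y <- chrom@signal
    n <- length(t)
    if (n < 3L) return(empty)
    base <- y[t <= t[1L] + 2]
    if (length(base) < 3L) base <- y[seq_len(min(n, 10L))]
    baseLevel <- median(base)
    thr <- 5 * mad(base)
    ## strict local maxima via the sign change of the first difference
    isMax <- which(diff(sign(diff(y))) < 0) + 1L
    isMax <- isMax[y[isMax] - baseLevel > thr & y[isMax] > baseLevel]
    if (!length(isMax)) return(empty)
    ## local minima (+ endpoints) delimit integration ranges
    minima <- c(1L, which(diff(sign(diff(y))) > 0) + 1L, n)
    rows <- lapply(isMax, function(i) {
        lo <- max(minima[minima < i])
        hi <- min(minima[minima > i])
        d <- abs(reference - t[i])
        sp <- if (min(d) <= tolerance) names(reference)[which.min(d)]
              else "unassigned"
        data.frame(species = sp, retention_time = t[i],
                   area = .trapz(t[lo:hi], y[lo:hi]), apex_height = y[i])
    })
    out <- do.call(rbind, rows)
    out[order(out$retention_time), , drop = FALSE]
}

#' Convert assigned HPLC peak areas to species concentrations
#'
#' Distributes a known total tetrapyrrole concentration over sirohaem (S1),
#' monodecarboxysirohaem (S2) and didecarboxysirohaem (S3) in proportion to
#' the assigned peak areas, providing kinetic-model inputs from a
#' chromatogram. Unassigned peaks are ignored. The result sums exactly to
#' `totalConc`.
#'
#' @param assignments Peak table from [assignHplcPeaks()].
#' @param totalConc Total tetrapyrrole concentration, uM (> 0).
#' @return Named numeric vector c(S1, S2, S3), uM.
#' @export
fractionsFromChromatogram <- function(assignments, totalConc) {
    stopifnot(is.data.frame(assignments),
              is.numeric(totalConc), length(totalConc) == 1L,
              totalConc > 0)
    keep <- assignments$species %in% names(.HPLC_REFERENCE)
    if (!any(keep))
        stop("no peak could be assigned to a tetrapyrrole species",
             call. = FALSE)
    areas <- c(SH = 0, MDSH = 0, DDSH = 0)
    agg <- tapply(assignments$area[keep], assignments$species[keep], sum)
    areas[names(agg)] <- agg
    v <- totalConc * areas / sum(areas)
    imax <- which.max(v)
    v[imax] <- totalConc - sum(v[-imax])   # exact closure of the total
    setNames(as.numeric(v), c("S1", "S2", "S3"))
}
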