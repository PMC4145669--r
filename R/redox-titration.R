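## One-electron Nernst analysis of a haem redox titration followed at a
## single wavelength (the 529 nm Q-band in the standard assay). The
## absorbance is a two-state mixture of the fully oxidized and fully
## reduced forms, with the reduced fraction set by the Nernst equation.

.FARADAY <- 96485.33212      # C/mol
.GASCONST <- 8.31446262      # J/(mol K)

## Nernst slope in 1/mV: n F / (R T), potentials in mV
.nernstBeta <- function(nElectrons, temperature) {
    nElectrons * .FARADAY / (.GASCONST * temperature * 1000)
}

#' Absorbance of a redox couple at a given potential
#'
#' Two-state Nernst model: the reduced fraction at applied potential E is
#' \eqn{1 / (1 + \exp(nF/(RT)\,(E - E_m)))}, so
#' \deqn{A(E) = A_{ox} + (A_{red} - A_{ox}) / (1 + e^{nF/(RT)(E - E_m)})}
#' with potentials in mV vs NHE. The curve moves one decade of the
#' oxidized/reduced ratio per ~59.16/n mV at 25 C, approaches `Ared` as
#' E decreases and `Aox` as E increases.
#'
#' @param E Applied potential(s), mV vs NHE.
#' @param fitpars A [NernstFit-class] (or the object returned by
#'   [fitNernst()]) holding Em, Aox, Ared, nElectrons and temperature.
#' @return Absorbance(s), AU.
#' @examples
#' pars <- NernstFit(Em = -98, Aox = 0.10, Ared = 0.35)
#' nernstAbsorbance(-98, pars)  # midpoint: (Aox + Ared)/2
#' @export
nernstAbsorbance <- function(E, fitpars) {
    stopifnot(is(fitpars, "NernstFit"))
    validObject(fitpars)
    beta <- .nernstBeta(fitpars@nElectrons, fitpars@temperature)
    fitpars@Aox + (fitpars@Ared - fitpars@Aox) /
        (1 + exp(beta * (as.numeric(E) - fitpars@Em)))
}

#' Fit the Nernst model to a redox titration curve
#'
#' Least-squares estimation of the midpoint potential `Em` and the two
#' asymptotic absorbances `Aox`, `Ared`, with the electron count fixed
#' (default 1, the Fe3+/Fe2+ couple). Starting values are taken from the
#' data (plateau means and the half-transition crossing), refined with
#' Levenberg-Marquardt; the fit is deterministic. No direction is assumed:
#' the reduced form may have the larger or the smaller absorbance.
#'
#' @param curve A [TitrationCurve-class]; potentials should span the
#'   transition (at least ~40 mV on either side of the apparent midpoint).
#' @param nElectrons Electrons of the couple, fixed during fitting
#'   (default 1).
#' @param temperature Temperature, K (default 298.15).
#' @return A [NernstFit-class] with estimates, standard errors and
#'   residuals.
#' @examples
#' pars <- NernstFit(Em = -98, Aox = 0.1, Ared = 0.35)
#' E <- seq(-300, 100, by = 10)
#' fit <- fitNernst(TitrationCurve(E, nernstAbsorbance(E, pars)))
#' midpointPotential(fit)
#' @export
fitNernst <- function(curve, nElectrons = 1L, temperature = 298.15) {
    stopifnot(is(curve, "TitrationCurve"))
    validObject(curve)
    ord <- order(curve@potentials)
    E <- curve@potentials[ord]
    A <- curve@absorbances[ord]
    span <- diff(range(A))
    if (span == 0)
        stop("no sigmoidal transition detectable: absorbance is constant ",
             "over the titrated range", call. = FALSE)
    beta <- .nernstBeta(as.integer(nElectrons), temperature)

    ## plateau/crossing starting values; low-E plateau is the reduced end
    k <- max(2L, length(E) %/% 5L)
    aRed0 <- mean(A[seq_len(k)])
    aOx0 <- mean(A[seq(length(A) - k + 1L, length(A))])
    if (aRed0 == aOx0) { aRed0 <- min(A); aOx0 <- max(A) }
    half <- (aRed0 + aOx0) / 2
    em0 <- E[which.min(abs(A - half))]

    resFn <- function(par) {
        model <- par[["Aox"]] + (par[["Ared"]] - par[["Aox"]]) /
            (1 + exp(beta * (E - par[["Em"]])))
        A - model
    }
    fit <- minpack.lm::nls.lm(par = c(Em = em0, Aox = aOx0, Ared = aRed0),
                              fn = resFn,
                              control = minpack.lm::nls.lm.control(
                                  maxiter = 500L))
    est <- fit$par
    resid <- resFn(est)
    rss <- sum(resid^2)
    if (abs(est[["Ared"]] - est[["Aox"]]) < 1e-3 * span ||
        sqrt(rss / length(A)) > 0.5 * span)
        stop("no sigmoidal transition detectable in the titrated range",
             call. = FALSE)
    dof <- max(length(A) - 3L, 1L)
    se <- tryCatch({
        covm <- rss / dof * solve(fit$hessian / 2)
        setNames(sqrt(pmax(diag(covm), 0)), c("Em", "Aox", "Ared"))
    }, error = function(e)
        setNames(rep(NA_real_, 3L), c("Em", "Aox", "Ared")))
    NernstFit(Em = est[["Em"]], Aox = est[["Aox"]], Ared = est[["Ared"]],
              nElectrons = as.integer(nElectrons), temperature = temperature,
              stdErrors = se, rss = rss, residuals = resid,
              converged = fit$info %in% 1:3)
}
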