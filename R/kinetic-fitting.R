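## Progress-curve fitting: all five constants are estimated simultaneously
## by Levenberg-Marquardt least squares on the simulated trajectories of the
## three species. Optimization is in natural-log parameter space, which
## enforces positivity without active bounds; standard errors are mapped
## back to natural units by the delta method.

.PARNAMES <- c("Km1", "Vmax1", "Km2", "Vmax2", "Ki")

## Collapse a replicate set to the fitting data: list(times, obs (n x 3),
## enzymeConc, nRep). 'mean' averages replicates point-wise (requires a
## common grid); 'joint' stacks them.
.prepareFitData <- function(data, replicates = c("mean", "joint")) {
    replicates <- match.arg(replicates)
    if (is(data, "TimeCourse")) data <- list(data)
    if (!length(data) || !all(vapply(data, is, logical(1), "TimeCourse")))
        stop("data must be a TimeCourse or a list of TimeCourse replicates",
             call. = FALSE)
    times <- timePoints(data[[1L]])
    if (!all(vapply(data, function(tc)
            isTRUE(all.equal(timePoints(tc), times)), logical(1))))
        stop("replicates must share a common time grid", call. = FALSE)
    ec <- unique(vapply(data, enzymeConc, numeric(1)))
    ec <- ec[!is.na(ec)]
    if (length(ec) > 1L)
        stop("replicates disagree on enzyme concentration", call. = FALSE)
    ec <- if (length(ec)) ec else NA_real_
    if (replicates == "mean" || length(data) == 1L) {
        obs <- Reduce(`+`, lapply(data, concentrations)) / length(data)
        list(times = times, obs = list(obs), enzymeConc = ec)
    } else {
        list(times = times, obs = lapply(data, concentrations),
             enzymeConc = ec)
    }
}

## Residual vector (observed - simulated), species-major within each
## replicate: S1 block, S2 block, S3 block.
.kineticResiduals <- function(logPar, prep, Eref, weights, rtol, atol) {
    p <- exp(logPar)
    params <- RateParameters(p[1L], p[2L], p[3L], p[4L], p[5L], Eref = Eref)
    ec <- if (is.na(prep$enzymeConc)) Eref else prep$enzymeConc
    init <- pmax(prep$obs[[1L]][1L, ], 0)
    if (length(prep$obs) > 1L)
        init <- pmax(Reduce(`+`, lapply(prep$obs, function(o) o[1L, ])) /
                         length(prep$obs), 0)
    sim <- concentrations(simulateTimeCourse(params, init, prep$times,
                                             enzymeConc = ec,
                                             rtol = rtol, atol = atol))
    unlist(lapply(prep$obs, function(o)
        as.vector((o - sim) * rep(weights, each = nrow(o)))),
        use.names = FALSE)
}

.speciesWeights <- function(prep, weighting) {
    if (weighting == "uniform") return(c(1, 1, 1))
    sds <- apply(do.call(rbind, prep$obs), 2L, sd)
    sds[sds <= 0] <- 1
    1 / sds
}

#' Fit the two-step kinetic model to progress-curve data
#'
#' Estimates the five constants (Km1, Vmax1, Km2, Vmax2, Ki) by nonlinear
#' least squares over the simulated ODE trajectories of all three species
#' simultaneously ([minpack.lm::nls.lm] in log-parameter space). Replicates
#' are averaged point-wise before fitting by default. A small deterministic
#' multistart (log-uniform perturbations of the guess, fixed seed) guards
#' against local minima; the best objective wins.
#'
#' The initial concentrations are taken from the first row of the (averaged)
#' data and are not fitted.
#'
#' @param data A [TimeCourse-class] or a list of replicate time courses on a
#'   common grid. At least 6 time points are required.
#' @param guess Starting [RateParameters-class]; its `Eref` is kept fixed.
#' @param weighting "uniform" (default) pools raw residuals over species;
#'   "per_species" scales each species' residuals by the reciprocal of its
#'   observed standard deviation.
#' @param replicates "mean" (default) fits the replicate average; "joint"
#'   fits all replicates simultaneously.
#' @param multistart Number of starting points including the guess
#'   (default 5).
#' @param seed RNG seed for the multistart perturbations (default 1).
#' @param maxEval Maximum optimizer iterations per start (default 200).
#' @param rtol,atol Integrator tolerances used inside the objective.
#' @return A [KineticFit-class] object. Non-convergence is flagged in
#'   `converged`/`message`, never silent.
#' @examples
#' truth <- ddAhbABParams()
#' tc <- simulateTimeCourse(truth, c(23, 0, 0))
#' fit <- fitTimeCourse(tc, guess = truth, multistart = 1)
#' paramVector(estimates(fit))
#' @export
fitTimeCourse <- function(data, guess,
                          weighting = c("uniform", "per_species"),
                          replicates = c("mean", "joint"),
                          multistart = 5L, seed = 1L, maxEval = 200L,
                          rtol = 1e-8, atol = 1e-10) {
    stopifnot(is(guess, "RateParameters"))
    validObject(guess)
    weighting <- match.arg(weighting)
    replicates <- match.arg(replicates)
    prep <- .prepareFitData(data, replicates)
    if (length(prep$times) < 6L)
        stop("at least 6 time points are required to fit the model",
             call. = FALSE)
    if (all(prep$obs[[1L]][1L, ] == 0))
        stop("at least one species must be non-zero initially", call. = FALSE)
    weights <- .speciesWeights(prep, weighting)
    logGuess <- log(paramVector(guess))

    starts <- list(logGuess)
    if (multistart > 1L) {
        old <- .Random.seed.save()
        set.seed(seed)
        for (k in seq_len(multistart - 1L))
            starts[[k + 1L]] <- logGuess +
                runif(5L, log(1 / 1.5), log(1.5))
        .Random.seed.restore(old)
    }

    ctrl <- minpack.lm::nls.lm.control(maxiter = as.integer(maxEval))
    startRSS <- sum(.kineticResiduals(logGuess, prep, guess@Eref, weights,
                                      rtol, atol)^2)
    best <- NULL
    for (s in starts) {
        fit <- tryCatch(
            minpack.lm::nls.lm(par = s, fn = .kineticResiduals, prep = prep,
                               Eref = guess@Eref, weights = weights,
                               rtol = rtol, atol = atol, control = ctrl),
            error = function(e) NULL)
        if (is.null(fit)) next
        if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
    if (is.null(best))
        stop("all optimizer starts failed; check data and guess",
             call. = FALSE)

    est <- exp(best$par)
    names(est) <- .PARNAMES
    pars <- RateParameters(est[1L], est[2L], est[3L], est[4L], est[5L],
                           Eref = guess@Eref)
    resid <- .kineticResiduals(best$par, prep, guess@Eref, weights, rtol, atol)
    names(resid) <- rep(rep(.SPECIES, each = length(prep$times)),
                        length(prep$obs))
    nObs <- length(resid)
    ok <- best$info %in% 1:3
    msg <- if (ok) "" else
        sprintf("optimizer did not report convergence (info = %d: %s)",
                best$info, best$message)
    covNat <- matrix(NA_real_, 5L, 5L, dimnames = list(.PARNAMES, .PARNAMES))
    se <- setNames(rep(NA_real_, 5L), .PARNAMES)
    lin <- .linearizedCovariance(best$par, prep, guess@Eref, weights,
                                 rtol, atol, sum(resid^2))
    if (!is.null(lin)) {
        covNat <- diag(est) %*% lin %*% diag(est)
        dimnames(covNat) <- list(.PARNAMES, .PARNAMES)
        se <- setNames(sqrt(pmax(diag(covNat), 0)), .PARNAMES)
    }
    new("KineticFit", estimates = pars, stdErrors = se,
        rss = best$deviance, residuals = resid, converged = ok,
        nObs = as.integer(nObs), covariance = covNat,
        startObjective = startRSS, message = msg)
}

## Save/restore .Random.seed so fitting never perturbs the caller's RNG
## stream beyond its own seeded draws.
.Random.seed.save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.Random.seed.restore <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
}

## Covariance of log-parameters from a finite-difference Jacobian of the
## residual vector, scaled by the residual variance. NULL when the normal
## matrix is numerically singular (with a warning naming the flat direction).
.linearizedCovariance <- function(logPar, prep, Eref, weights, rtol, atol,
                                  rss) {
    r0 <- .kineticResiduals(logPar, prep, Eref, weights, rtol, atol)
    n <- length(r0); p <- length(logPar)
    h <- 1e-6
    J <- matrix(0, n, p)
    for (j in seq_len(p)) {
        up <- logPar; up[j] <- up[j] + h
        dn <- logPar; dn[j] <- dn[j] - h
        J[, j] <- (.kineticResiduals(up, prep, Eref, weights, rtol, atol) -
                   .kineticResiduals(dn, prep, Eref, weights, rtol, atol)) /
                  (2 * h)
    }
    JtJ <- crossprod(J)
    ev <- eigen(JtJ, symmetric = TRUE)
    if (!all(is.finite(ev$values)) || max(ev$values) <= 0 ||
        min(ev$values) < max(ev$values) * 1e-12) {
        flat <- ev$vectors[, which.min(ev$values)]
        names(flat) <- .PARNAMES
        worst <- names(sort(abs(flat), decreasing = TRUE))[1:2]
        warning(sprintf(
            "parameter combination poorly identified (direction dominated by %s)",
            paste(worst, collapse = ", ")), call. = FALSE)
        return(NULL)
    }
    sigma2 <- rss / max(n - p, 1L)
    sigma2 * solve(JtJ)
}

#' Standard errors for a progress-curve fit
#'
#' Linearized errors come from the finite-difference Jacobian of the model
#' residuals at the optimum (inverse normal matrix scaled by the residual
#' variance, delta-method back-transform from log space). Bootstrap errors
#' come from residual-resampling refits, each started at the fitted values;
#' deterministic given `seed`.
#'
#' @param fit A converged [KineticFit-class].
#' @param data The data the fit was produced from (same form as in
#'   [fitTimeCourse()]).
#' @param method "linearized" or "bootstrap".
#' @param nBoot Number of bootstrap resamples (required > 0 for bootstrap).
#' @param seed RNG seed for the bootstrap.
#' @param replicates Replicate handling, as in [fitTimeCourse()].
#' @return Named numeric vector of per-parameter standard errors in natural
#'   units; for the bootstrap, the matrix of resampled estimates is attached
#'   as attribute `"samples"`.
#' @export
estimateUncertainty <- function(fit, data,
                                method = c("linearized", "bootstrap"),
                                nBoot = 200L, seed = 1L,
                                replicates = c("mean", "joint")) {
    stopifnot(is(fit, "KineticFit"))
    method <- match.arg(method)
    replicates <- match.arg(replicates)
    if (!isTRUE(fit@converged))
        stop("uncertainty is only defined for a converged fit", call. = FALSE)
    if (method == "linearized") {
        prep <- .prepareFitData(data, replicates)
        weights <- c(1, 1, 1)
        logPar <- log(paramVector(fit@estimates))
        lin <- .linearizedCovariance(logPar, prep, fit@estimates@Eref,
                                     weights, 1e-8, 1e-10, fit@rss)
        if (is.null(lin))
            return(setNames(rep(NA_real_, 5L), .PARNAMES))
        est <- paramVector(fit@estimates)
        covNat <- diag(est) %*% lin %*% diag(est)
        return(setNames(sqrt(pmax(diag(covNat), 0)), .PARNAMES))
    }
    if (!is.numeric(nBoot) || nBoot < 1L)
        stop("bootstrap requires nBoot >= 1", call. = FALSE)
    ## the bootstrap operates on the replicate-mean data
    prep <- .prepareFitData(data, "mean")
    nT <- length(prep$times)
    fitted <- lapply(prep$obs, function(o)
        o - matrix(head(fit@residuals, 3L * nT), nT, 3L))
    ## residual pool from the fit, resampled with replacement per bootstrap
    pool <- fit@residuals
    old <- .Random.seed.save()
    set.seed(seed)
    samples <- matrix(NA_real_, nBoot, 5L,
                      dimnames = list(NULL, .PARNAMES))
    for (b in seq_len(nBoot)) {
        rb <- sample(pool, length(pool), replace = TRUE)
        obsB <- pmax(fitted[[1L]] + matrix(rb[seq_len(3L * nT)], nT, 3L), 0)
        ## keep the fixed initial row so S1(0) is not resampled away
        obsB[1L, ] <- prep$obs[[1L]][1L, ]
        tcB <- TimeCourse(prep$times, obsB, enzymeConc = prep$enzymeConc)
        fb <- tryCatch(
            fitTimeCourse(tcB, guess = fit@estimates, multistart = 1L,
                          maxEval = 100L),
            error = function(e) NULL)
        if (!is.null(fb)) samples[b, ] <- paramVector(estimates(fb))
    }
    .Random.seed.restore(old)
    se <- apply(samples, 2L, sd, na.rm = TRUE)
    attr(se, "samples") <- samples
    se
}

#' Goodness-of-fit summary for a progress-curve fit
#'
#' @param fit A converged [KineticFit-class].
#' @return A list with `perSpecies` (RMSE per species, uM), `total`
#'   (pooled RMSE, uM) and `residualTable` (species, index, residual) for
#'   plotting. The per-species sums of squares add up to the total.
#' @export
goodnessOfFit <- function(fit) {
    stopifnot(is(fit, "KineticFit"))
    if (!isTRUE(fit@converged))
        stop("goodness of fit requires a converged fit", call. = FALSE)
    r <- fit@residuals
    n <- length(r)
    species <- if (!is.null(names(r)) && all(names(r) %in% .SPECIES))
        names(r)
    else rep(rep(.SPECIES, each = n %/% 3L), length.out = n)
    perSS <- tapply(r^2, species, sum)[c("S1", "S2", "S3")]
    nPer <- tapply(r, species, length)[c("S1", "S2", "S3")]
    perRMSE <- setNames(sqrt(as.vector(perSS) / as.vector(nPer)),
                        c("S1", "S2", "S3"))
    list(perSpecies = perRMSE,
         total = sqrt(sum(r^2) / n),
         residualTable = data.frame(species = species,
                                    index = seq_len(n),
                                    residual = r))
}
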