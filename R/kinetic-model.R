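## Two-step decarboxylation cascade with a single active site:
##   S1 --v1--> S2 --v2--> S3
## Each rate is Michaelis-Menten in its own substrate with competitive
## inhibition by the other substrate (through its own Km) and by the
## tight-binding product (through Ki):
##   v1 = (Vmax1 E/Eref) S1 / (Km1 (1 + S2/Km2 + S3f/Ki) + S1)
##   v2 = (Vmax2 E/Eref) S2 / (Km2 (1 + S1/Km1 + S3f/Ki) + S2)
## Because Ki is comparable to the enzyme concentration, the product term
## uses the FREE product concentration S3f from the Morrison binary-binding
## quadratic rather than total S3: enzyme-bound product is appreciable and
## must not be counted as free inhibitor. This also makes all five
## constants identifiable from a single mass-conserving progress curve;
## with total S3 the conservation constraint S3 = T - S1 - S2 collapses
## both denominators to affine forms with a free common scale, leaving an
## exact one-parameter family of indistinguishable fits.
## Vmax values are stored at the reference enzyme concentration Eref and
## scale linearly with the assay enzyme concentration.

## Free product concentration: S3f = S3 - [E.S3], with [E.S3] the root of
## the binding quadratic for total enzyme E0 and dissociation constant Ki.
.freeProduct <- function(S3, Ki, E0) {
    if (S3 <= 0) return(0)
    b <- E0 + S3 + Ki
    es <- (b - sqrt(b * b - 4 * E0 * S3)) / 2
    max(S3 - es, 0)
}

.checkState <- function(state) {
    state <- as.numeric(state)
    if (length(state) != 3L || anyNA(state))
        stop("state must be three concentrations (S1, S2, S3)", call. = FALSE)
    if (any(state < 0))
        stop("concentrations must be non-negative", call. = FALSE)
    state
}

.checkEnzyme <- function(enzymeConc) {
    if (!is.numeric(enzymeConc) || length(enzymeConc) != 1L ||
        is.na(enzymeConc) || enzymeConc <= 0)
        stop("enzymeConc must be a positive scalar, uM", call. = FALSE)
    enzymeConc
}

#' Decarboxylation rates of the two-step competitive-inhibition model
#'
#' `rateV1` is the rate of sirohaem (S1) decarboxylation, `rateV2` the rate
#' of monodecarboxysirohaem (S2) decarboxylation. Each follows a
#' single-active-site competitive model: the other substrate competes
#' through its own Michaelis constant and the product didecarboxysirohaem
#' (S3) inhibits through the tight-binding constant `Ki`:
#' \deqn{v_1 = \frac{V_{max1} (E/E_{ref}) \, S_1}{K_{m1}(1 + S_2/K_{m2} + S_3^{free}/K_i) + S_1}}
#' \deqn{v_2 = \frac{V_{max2} (E/E_{ref}) \, S_2}{K_{m2}(1 + S_1/K_{m1} + S_3^{free}/K_i) + S_2}}
#' Because `Ki` is of the order of the enzyme concentration the product is
#' a tight-binding inhibitor: a substantial fraction of it is
#' enzyme-bound, so the inhibition term uses the free product
#' concentration from the Morrison binding quadratic,
#' \eqn{S_3^{free} = S_3 - [ES_3]} with
#' \eqn{[ES_3] = ((E_0+S_3+K_i) - \sqrt{(E_0+S_3+K_i)^2 - 4E_0S_3})/2}.
#' As \eqn{K_i \to \infty} (no product binding) the rates reduce to the
#' classical two-substrate competitive form.
#'
#' @param params A [RateParameters-class] object.
#' @param state Concentrations (S1, S2, S3) in uM; numeric vector of length 3,
#'   all non-negative.
#' @param enzymeConc Enzyme concentration of the assay, uM (default the
#'   reference concentration of `params`).
#' @return Reaction rate, uM/min.
#' @examples
#' p <- ddAhbABParams()
#' rateV1(p, c(23, 0, 0))          # initial rate of the standard assay
#' rateV1(p, c(p@Km1, 0, 0))       # half of Vmax1
#' @export
rateV1 <- function(params, state, enzymeConc = params@Eref) {
    stopifnot(is(params, "RateParameters"))
    validObject(params)
    state <- .checkState(state)
    .checkEnzyme(enzymeConc)
    if (state[1L] == 0) return(0)
    f3 <- .freeProduct(state[3L], params@Ki, enzymeConc)
    denom <- params@Km1 * (1 + state[2L] / params@Km2 + f3 / params@Ki) +
        state[1L]
    params@Vmax1 * (enzymeConc / params@Eref) * state[1L] / denom
}

#' @rdname rateV1
#' @export
rateV2 <- function(params, state, enzymeConc = params@Eref) {
    stopifnot(is(params, "RateParameters"))
    validObject(params)
    state <- .checkState(state)
    .checkEnzyme(enzymeConc)
    if (state[2L] == 0) return(0)
    f3 <- .freeProduct(state[3L], params@Ki, enzymeConc)
    denom <- params@Km2 * (1 + state[1L] / params@Km1 + f3 / params@Ki) +
        state[2L]
    params@Vmax2 * (enzymeConc / params@Eref) * state[2L] / denom
}

## Right-hand side for deSolve; states clipped at 0 so transient
## sub-tolerance negatives cannot poison the rate denominators.
.odeRHS <- function(t, y, parms) {
    y <- pmax(y, 0)
    s1 <- y[1L]; s2 <- y[2L]; s3 <- y[3L]
    scale <- parms$scale
    f3 <- .freeProduct(s3, parms$Ki, parms$E0)
    v1 <- if (s1 > 0)
        parms$Vmax1 * scale * s1 /
            (parms$Km1 * (1 + s2 / parms$Km2 + f3 / parms$Ki) + s1) else 0
    v2 <- if (s2 > 0)
        parms$Vmax2 * scale * s2 /
            (parms$Km2 * (1 + s1 / parms$Km1 + f3 / parms$Ki) + s2) else 0
    list(c(-v1, v1 - v2, v2))
}

#' Default sampling grid for progress-curve simulations
#'
#' 16 points over 0-120 min, geometrically spaced after t = 0 so the early
#' transient of the intermediate is well resolved.
#'
#' @param tMax Final time, minutes (default 120).
#' @param n Number of points including t = 0 (default 16).
#' @param tFirst First non-zero time, minutes (default 0.5).
#' @return Numeric vector of times, strictly increasing from 0.
#' @export
defaultKineticTimes <- function(tMax = 120, n = 16L, tFirst = 0.5) {
    stopifnot(n >= 3L, tFirst > 0, tMax > tFirst)
    c(0, exp(seq(log(tFirst), log(tMax), length.out = n - 1L)))
}

#' Simulate a decarboxylation progress curve
#'
#' Integrates the mass-conserving ODE system dS1/dt = -v1,
#' dS2/dt = v1 - v2, dS3/dt = v2 with an adaptive stiff-capable solver
#' ([deSolve::lsoda]). Sub-tolerance negative values are clipped to zero in
#' the returned trajectory.
#'
#' @param params A [RateParameters-class] object.
#' @param initial Initial concentrations (S1, S2, S3), uM.
#' @param times Output times, minutes; strictly increasing from 0.
#' @param enzymeConc Assay enzyme concentration, uM (default `params@Eref`).
#' @param rtol,atol Relative / absolute integrator tolerances (defaults
#'   1e-8 and 1e-10 uM; conservation then holds to well below 1e-6 uM).
#' @return A [TimeCourse-class] object.
#' @examples
#' tc <- simulateTimeCourse(ddAhbABParams(), c(23, 0, 0))
#' head(as.data.frame(tc))
#' @export
simulateTimeCourse <- function(params, initial, times = defaultKineticTimes(),
                               enzymeConc = params@Eref,
                               rtol = 1e-8, atol = 1e-10) {
    stopifnot(is(params, "RateParameters"))
    validObject(params)
    initial <- .checkState(initial)
    .checkEnzyme(enzymeConc)
    times <- as.numeric(times)
    if (length(times) < 1L || times[1L] != 0 ||
        (length(times) > 1L && any(diff(times) <= 0)))
        stop("times must be strictly increasing from 0", call. = FALSE)
    parms <- list(Km1 = params@Km1, Vmax1 = params@Vmax1, Km2 = params@Km2,
                  Vmax2 = params@Vmax2, Ki = params@Ki,
                  scale = enzymeConc / params@Eref, E0 = enzymeConc)
    sol <- deSolve::lsoda(y = c(S1 = initial[1L], S2 = initial[2L],
                                S3 = initial[3L]),
                          times = times, func = .odeRHS, parms = parms,
                          rtol = rtol, atol = atol)
    diag <- attr(sol, "istate")
    if (!is.null(diag) && diag[1L] < 0)
        stop(sprintf("ODE integration failed (lsoda istate = %d)", diag[1L]),
             call. = FALSE)
    states <- unclass(sol)[, c("S1", "S2", "S3"), drop = FALSE]
    states[states < 0 & states > -10 * atol] <- 0
    states <- pmax(states, 0)
    TimeCourse(times = times, states = states, enzymeConc = enzymeConc)
}

#' Mass-conservation residual of a time course
#'
#' The cascade converts S1 to S3 via S2 without loss, so the total
#' tetrapyrrole concentration S1 + S2 + S3 is invariant. Returns the largest
#' absolute deviation of the total from its initial value; for simulated
#' trajectories this is bounded by the integrator tolerance, for noisy data
#' it is of the order of the observation noise.
#'
#' @param tc A [TimeCourse-class] object.
#' @return Maximum absolute deviation of the total from its t = 0 value, uM.
#' @export
conservationResidual <- function(tc) {
    stopifnot(is(tc, "TimeCourse"))
    validObject(tc)
    tot <- rowSums(concentrations(tc))
    max(abs(tot - tot[1L]))
}
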