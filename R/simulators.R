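# Three canonical switching mechanisms, as minimal simulators: a planar
# slow-fast system with a hysteresis loop, coupled forced double-well
# oscillators with intermingled basin structure, and a stochastic robust
# heteroclinic cycle on the 3-sphere. Deterministic systems are integrated
# with fixed-step classical RK4 (deSolve); the stochastic system with an
# RK4 drift plus Euler-Maruyama Brownian step.

.odeCheckFinite <- function(sol) {
    bad <- which(!apply(is.finite(sol), 1L, all))
    if (length(bad))
        stop(sprintf("integration blew up at t = %.4f", sol[bad[1L], 1L]))
    invisible(sol)
}

.subsampleSolution <- function(sol, sampleEvery, cols) {
    keep <- seq(1L, nrow(sol), by = sampleEvery)
    list(values = unname(sol[keep, cols, drop = FALSE]),
         times = unname(sol[keep, 1L]))
}

#' Configuration of the slow-fast hysteresis simulator
#'
#' A planar system with one slow variable x1 and one fast variable x2.
#' The fast nullcline (critical manifold) consists of two near-horizontal
#' activity branches x2 = b + nu * x1 and x2 = c + nu * x1 and the tilted
#' line x2 = alpha * x1 + beta, intersecting them in transcritical points;
#' the fast subsystem therefore carries a hysteresis loop with two stable
#' levels of activity. The slow drift \code{dx1/dt = epsTimescale *
#' (a - x2)} moves the system along one branch until the branch loses
#' stability, producing relaxation alternation between the two metastable
#' levels:
#' \deqn{dx_1/dt = \epsilon (a - x_2), \quad
#'       dx_2/dt = -(x_2 - b - \nu x_1)(x_2 - c - \nu x_1)
#'                  (x_2 - \alpha x_1 - \beta).}
#' The small branch slope nu (\code{branchSlope}) is a structural
#' regularization: with exactly horizontal branches the branches are
#' invariant lines of the flow and a trajectory reaching one can never
#' jump off it (the exchange-of-stability delay at the transcritical
#' point is unbounded). A small negative slope makes the trajectory trail
#' the moving branch on the side facing the other branch, so every
#' transcritical crossing deterministically triggers the jump.
#'
#' @param a slow drift target.
#' @param b,c the two stable fast activity levels.
#' @param alpha,beta slope and offset of the tilted nullcline branch.
#' @param branchSlope small slope nu of the two activity branches.
#' @param epsTimescale timescale separation 0 < eps << 1 (distinct from
#'   the recurrence ball size).
#' @param angleDrift optional relative modulation of the tilted-branch
#'   slope, \code{alpha * (1 + angleDrift * sin(2 pi t / anglePeriod))};
#'   default off (0). Emulates slow fluctuations varying dwell times.
#' @param anglePeriod period of the slope modulation (time units).
#' @param initialState named or unnamed c(x1, x2) start point.
#' @param tEnd,dt integration horizon and fixed step.
#' @param sampleEvery keep every k-th integration step in the output.
#' @return a validated configuration list of class "SlowFastConfig".
#' @export
slowFastConfig <- function(a = 0.3, b = -1, c = 1, alpha = -2,
                           beta = -0.5, epsTimescale = 0.004,
                           branchSlope = -0.05, angleDrift = 0,
                           anglePeriod = 1000,
                           initialState = c(x1 = 0, x2 = 1),
                           tEnd = 6000, dt = 0.05, sampleEvery = 100L) {
    if (epsTimescale <= 0)
        stop("slowFastConfig: 'epsTimescale' must be positive")
    if (dt <= 0) stop("slowFastConfig: 'dt' must be positive")
    structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                   epsTimescale = epsTimescale,
                   branchSlope = branchSlope, angleDrift = angleDrift,
                   anglePeriod = anglePeriod,
                   initialState = unname(initialState), tEnd = tEnd,
                   dt = dt, sampleEvery = as.integer(sampleEvery)),
              class = "SlowFastConfig")
}

#' Simulate the slow-fast hysteresis system
#'
#' @param cfg a [slowFastConfig()].
#' @return a 2-column \linkS4class{StateTrajectory} (x1, x2) with the
#'   integration times in \code{attr(, "times")} and the configuration in
#'   \code{attr(, "config")}.
#' @export
simulateSlowFast <- function(cfg = slowFastConfig()) {
    stopifnot(inherits(cfg, "SlowFastConfig"))
    rhs <- function(t, y, parms) {
        alphaT <- cfg$alpha
        if (cfg$angleDrift != 0)
            alphaT <- cfg$alpha *
                (1 + cfg$angleDrift * sin(2 * pi * t / cfg$anglePeriod))
        dx1 <- cfg$epsTimescale * (cfg$a - y[2L])
        dx2 <- -(y[2L] - cfg$b - cfg$branchSlope * y[1L]) *
            (y[2L] - cfg$c - cfg$branchSlope * y[1L]) *
            (y[2L] - alphaT * y[1L] - cfg$beta)
        list(c(dx1, dx2))
    }
    sol <- deSolve::ode(y = cfg$initialState,
                        times = seq(0, cfg$tEnd, by = cfg$dt),
                        func = rhs, parms = NULL, method = "rk4")
    .odeCheckFinite(sol)
    sub <- .subsampleSolution(sol, cfg$sampleEvery, 2:3)
    colnames(sub$values) <- c("x1", "x2")
    out <- stateTrajectory(sub$values,
                           sampleInterval = cfg$dt * cfg$sampleEvery)
    attr(out, "times") <- sub$times
    attr(out, "config") <- cfg
    out
}

#' Configuration of the intermingled-basins simulator
#'
#' Two coupled second-order oscillators with a sinusoidal forcing. The
#' first oscillator moves in the symmetric double well V(x) = x^4/4 -
#' x^2/2 under damping mu; the slow sinusoidal forcing A sin(omega t),
#' with amplitude above the static escape threshold 2/(3 sqrt(3)),
#' periodically sweeps the basin structure so that one well after the
#' other loses stability and the trajectory switches between the two
#' well regions -- the two metastable states. The second oscillator has
#' the stiffer double-well potential V(x) = alpha x^2/2 + x^4/4 (wells
#' at +/- 2 for alpha = -4), is driven by the first through p and feeds
#' back weakly through its velocity (q), keeping the two wells of the
#' first oscillator exactly symmetric:
#' \deqn{\ddot x_1 = -\mu \dot x_1 + x_1 - x_1^3 + q \dot x_2
#'       + A \sin(\omega t),}
#' \deqn{\ddot x_2 = -\mu \dot x_2 - (\alpha x_2 + x_2^3)
#'       + p (x_1 - x_2).}
#'
#' @param A forcing amplitude; 0 gives the autonomous bistable limit
#'   (no switching).
#' @param mu damping of both oscillators.
#' @param alpha linear stiffness of the second oscillator's potential.
#' @param p,q coupling strengths (first into second / second's velocity
#'   into first).
#' @param forcingOmega angular frequency of the sinusoidal forcing; slow
#'   compared to both oscillators so dwell episodes are long.
#' @param initialState c(x1, v1, x2, v2) start point.
#' @param tEnd,dt,sampleEvery integration horizon, fixed step and output
#'   thinning.
#' @return a validated configuration list of class "RiddledConfig".
#' @export
riddledConfig <- function(A = 1.011, mu = 0.632, alpha = -4, p = 0.1,
                          q = 0.005, forcingOmega = 0.03,
                          initialState = c(x1 = 1, v1 = 0, x2 = 2, v2 = 0),
                          tEnd = 6000, dt = 0.05, sampleEvery = 100L) {
    if (dt <= 0) stop("riddledConfig: 'dt' must be positive")
    structure(list(A = A, mu = mu, alpha = alpha, p = p, q = q,
                   forcingOmega = forcingOmega,
                   initialState = unname(initialState), tEnd = tEnd,
                   dt = dt, sampleEvery = as.integer(sampleEvery)),
              class = "RiddledConfig")
}

#' Simulate the intermingled-basins system
#'
#' Both second-order equations are reduced to first-order pairs and
#' integrated with fixed-step RK4.
#'
#' @param cfg a [riddledConfig()].
#' @return a 4-column \linkS4class{StateTrajectory} (x1, v1, x2, v2) with
#'   times and configuration attached as attributes.
#' @export
simulateRiddled <- function(cfg = riddledConfig()) {
    stopifnot(inherits(cfg, "RiddledConfig"))
    rhs <- function(t, y, parms) {
        list(c(y[2L],
               -cfg$mu * y[2L] + y[1L] - y[1L]^3 + cfg$q * y[4L] +
                   cfg$A * sin(cfg$forcingOmega * t),
               y[4L],
               -cfg$mu * y[4L] - (cfg$alpha * y[3L] + y[3L]^3) +
                   cfg$p * (y[1L] - y[3L])))
    }
    sol <- deSolve::ode(y = cfg$initialState,
                        times = seq(0, cfg$tEnd, by = cfg$dt),
                        func = rhs, parms = NULL, method = "rk4")
    .odeCheckFinite(sol)
    sub <- .subsampleSolution(sol, cfg$sampleEvery, 2:5)
    colnames(sub$values) <- c("x1", "v1", "x2", "v2")
    out <- stateTrajectory(sub$values,
                           sampleInterval = cfg$dt * cfg$sampleEvery)
    attr(out, "times") <- sub$times
    attr(out, "config") <- cfg
    out
}

#' Configuration of the heteroclinic-cycle simulator
#'
#' A four-dimensional system on the 3-sphere with a robust stable
#' heteroclinic cycle between the two saddle equilibria (0, 0, 0, +/-1).
#' An ambient field g is projected onto the sphere's tangent space,
#' \code{dx/dt = g - (x . g) x}, with
#' \deqn{g_1 = (\alpha_1 x_4 + \alpha_2) x_1, \quad
#'       g_2 = (-\alpha_1 x_4 + \alpha_2) x_2, \quad
#'       g_3 = \alpha_2 x_3, \quad g_4 = b (x_2^2 - x_1^2).}
#' Near the north pole x1 grows and x2 contracts (and vice versa at the
#' south pole), and the b-coupling carries the state across the equator,
#' closing the pole-to-pole cycle. The contraction rate |−alpha1 + alpha2|
#' exceeds the expansion rate alpha1 + alpha2, so the noise-free cycle is
#' attracting and successive passage times increase monotonically. Noise
#' enters the fourth equation only, as an Euler-Maruyama Brownian term
#' with the growing amplitude \code{noiseA * (1 + t)}, which counteracts
#' the slowing of the deterministic cycle; noisy steps are renormalized
#' onto the sphere.
#'
#' @param alpha1 primary growth/contraction rate of the two transverse
#'   channels.
#' @param alpha2 weak uniform contraction (negative).
#' @param b transverse-to-polar coupling closing the cycle.
#' @param noiseA base amplitude of the Brownian term (0 = deterministic).
#' @param initialState unit-norm start point on the 3-sphere; the default
#'   sits near the north-pole saddle with small transverse components.
#' @param tEnd,dt,sampleEvery integration horizon, fixed step and output
#'   thinning.
#' @param seed integer seed for the Brownian increments.
#' @return a validated configuration list of class "HeteroclinicConfig".
#' @export
heteroclinicConfig <- function(alpha1 = 1, alpha2 = -0.1, b = 0.33,
                               noiseA = 5e-5,
                               initialState = c(0.01, 0.005, 0.002,
                                                sqrt(1 - 0.01^2 -
                                                     0.005^2 - 0.002^2)),
                               tEnd = 400, dt = 1e-3, sampleEvery = 300L,
                               seed = 1L) {
    if (dt <= 0) stop("heteroclinicConfig: 'dt' must be positive")
    x0 <- unname(initialState)
    if (length(x0) != 4L || abs(sqrt(sum(x0^2)) - 1) > 1e-8)
        stop("heteroclinicConfig: initial state must be unit-norm in R^4")
    structure(list(alpha1 = alpha1, alpha2 = alpha2, b = b,
                   noiseA = noiseA, initialState = x0, tEnd = tEnd,
                   dt = dt, sampleEvery = as.integer(sampleEvery),
                   seed = as.integer(seed)),
              class = "HeteroclinicConfig")
}

#' Deterministic drift of the heteroclinic system
#'
#' Exposed so the saddle equilibria can be verified directly: the drift
#' vanishes exactly at (0, 0, 0, +/-1).
#'
#' @param x unit-norm 4-vector.
#' @param cfg a [heteroclinicConfig()].
#' @return the 4-dimensional drift vector.
#' @export
heteroclinicDrift <- function(x, cfg = heteroclinicConfig()) {
    g <- c((cfg$alpha1 * x[4L] + cfg$alpha2) * x[1L],
           (-cfg$alpha1 * x[4L] + cfg$alpha2) * x[2L],
           cfg$alpha2 * x[3L],
           cfg$b * (x[2L]^2 - x[1L]^2))
    g - sum(x * g) * x
}

#' Simulate the heteroclinic-cycle system
#'
#' @param cfg a [heteroclinicConfig()].
#' @return a 4-column \linkS4class{StateTrajectory} (x1..x4) with times
#'   and configuration attached as attributes. Noise-free runs stay on
#'   the unit 3-sphere up to integration error.
#' @export
simulateHeteroclinic <- function(cfg = heteroclinicConfig()) {
    stopifnot(inherits(cfg, "HeteroclinicConfig"))
    set.seed(cfg$seed)
    nSteps <- round(cfg$tEnd / cfg$dt)
    res <- .heteroclinic_integrate(cfg$initialState, cfg$alpha1,
                                   cfg$alpha2, cfg$b, cfg$noiseA, cfg$dt,
                                   as.integer(nSteps), cfg$sampleEvery)
    values <- res$values
    colnames(values) <- c("x1", "x2", "x3", "x4")
    out <- stateTrajectory(values,
                           sampleInterval = cfg$dt * cfg$sampleEvery)
    attr(out, "times") <- res$times
    attr(out, "config") <- cfg
    out
}

#' Passage episodes of a heteroclinic trajectory
#'
#' Splits a simulated heteroclinic trajectory into contiguous episodes
#' during which the state stays within a polar cap (|x4| > threshold) of
#' one of the two saddles, and reports their durations. For noise-free
#' runs the durations of complete interior episodes are non-decreasing, a
#' signature of an attracting heteroclinic cycle.
#'
#' @param traj a \linkS4class{StateTrajectory} from
#'   [simulateHeteroclinic()] (needs the "times" attribute).
#' @param threshold polar-cap boundary on |x4|.
#' @return data.frame with columns pole (+1/-1), start, end and duration
#'   (time units), one row per completed passage (the truncated final
#'   episode is dropped).
#' @export
heteroclinicPassages <- function(traj, threshold = 0.99) {
    v <- trajValues(traj)
    times <- attr(traj, "times")
    if (is.null(times)) stop("heteroclinicPassages: missing times attribute")
    inCap <- abs(v[, 4L]) > threshold
    pole <- sign(v[, 4L])
    r <- rle(ifelse(inCap, pole, 0))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values != 0)
    keep <- keep[ends[keep] < length(inCap)]   # drop truncated final cap
    data.frame(pole = r$values[keep],
               start = times[starts[keep]],
               end = times[ends[keep]],
               duration = times[ends[keep]] - times[starts[keep]])
}
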