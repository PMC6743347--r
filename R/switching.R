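# Ground-truthed metastable switching surrogate for module-averaged BOLD
# ensembles.

.unitize <- function(v) v / sqrt(sum(v^2))

# Spherical linear interpolation between unit vectors.
.slerp <- function(a, b, f) {
    ang <- acos(max(-1, min(1, sum(a * b))))
    if (ang < 1e-12) return(a)
    (sin((1 - f) * ang) * a + sin(f * ang) * b) / sin(ang)
}

#' Configuration of the metastable switching generator
#'
#' Defaults emulate the shape of module-averaged resting-state BOLD
#' recordings: T = 1200 samples in M = 40 dimensions, a handful of
#' metastable states with mean dwell of 40 samples, unit-hypersphere
#' normalization, and brief transients between dwell epochs.
#'
#' @param nModules state dimension M.
#' @param nStates number of metastable states.
#' @param T number of samples per trajectory.
#' @param meanDwell mean dwell epoch length (samples; geometric).
#' @param transientLen number of transient samples per state switch.
#' @param noiseSigma isotropic noise standard deviation around centers.
#' @param minCenterAngle minimal pairwise angle between state centers
#'   (radians).
#' @param transitJitter amplitude of the random deflection of transient
#'   samples away from the great-circle path (see
#'   [generateSwitchingEnsemble()]).
#' @param seed integer seed.
#' @return a validated configuration list of class "SwitchingConfig".
#' @export
switchingConfig <- function(nModules = 40L, nStates = 3L, T = 1200L,
                            meanDwell = 40L, transientLen = 1L,
                            noiseSigma = 0.05, minCenterAngle = pi / 3,
                            transitJitter = 1, seed = 1L) {
    cfg <- list(nModules = as.integer(nModules),
                nStates = as.integer(nStates), T = as.integer(T),
                meanDwell = as.integer(meanDwell),
                transientLen = as.integer(transientLen),
                noiseSigma = noiseSigma,
                minCenterAngle = minCenterAngle,
                transitJitter = transitJitter, seed = as.integer(seed))
    if (cfg$nStates < 1L) stop("switchingConfig: need at least one state")
    if (cfg$noiseSigma < 0) stop("switchingConfig: 'noiseSigma' must be >= 0")
    if (cfg$T < cfg$nStates * (cfg$meanDwell + cfg$transientLen))
        stop("switchingConfig: T too short for the requested epochs")
    class(cfg) <- "SwitchingConfig"
    cfg
}

# Draw nStates unit centers with pairwise angle >= minCenterAngle.
# Rejection sampling first; when the requested separation is too rare to
# hit by chance (e.g. near-antipodal center pairs), the last draw is
# pushed apart by spherical repulsion until the constraint holds.
.drawCenters <- function(nStates, nModules, minCenterAngle,
                         maxTries = 200L) {
    maxCos <- cos(minCenterAngle)
    ok <- function(centers) {
        gram <- tcrossprod(centers)
        nStates == 1L || max(gram[upper.tri(gram)]) <= maxCos
    }
    centers <- NULL
    for (tries in seq_len(maxTries)) {
        centers <- matrix(rnorm(nStates * nModules), nStates, nModules)
        centers <- centers / sqrt(rowSums(centers^2))
        if (ok(centers)) return(centers)
    }
    for (iter in seq_len(500L)) {
        gram <- tcrossprod(centers)
        diag(gram) <- -1
        worst <- which(gram == max(gram), arr.ind = TRUE)[1L, ]
        i <- worst[1L]; j <- worst[2L]
        ci <- centers[i, ]; cj <- centers[j, ]
        centers[i, ] <- .unitize(ci - 0.2 * cj)
        centers[j, ] <- .unitize(cj - 0.2 * ci)
        if (ok(centers)) return(centers)
    }
    stop(sprintf(
        "cannot pack %d centers with pairwise angle >= %.2f rad in %d dimensions",
        nStates, minCenterAngle, nModules))
}

# State visit order: concatenated random permutations, fixed up so no
# state immediately repeats; guarantees every state is visited.
.epochOrder <- function(nStates, nEpochs) {
    if (nStates == 1L) return(rep(1L, nEpochs))
    order <- integer(0)
    while (length(order) < nEpochs) {
        perm <- sample.int(nStates)
        if (length(order) && perm[1L] == order[length(order)]) {
            k <- sample(2:nStates, 1L)
            perm[c(1L, k)] <- perm[c(k, 1L)]
        }
        order <- c(order, perm)
    }
    order[seq_len(nEpochs)]
}

#' Generate a ground-truthed switching ensemble
#'
#' Draws \code{nStates} well-separated unit centers shared by all
#' subjects. Each subject's trajectory alternates dwell epochs (geometric
#' length, mean \code{meanDwell}) around a center -- center plus isotropic
#' Gaussian noise, re-normalized -- with short transients between
#' consecutive centers. Transient samples are placed along the great
#' circle between the two centers and deflected by an independent random
#' unit direction scaled by \code{transitJitter * sin(pi * f)} (f the
#' interpolation fraction), so distinct crossings are not mutually
#' recurrent and genuinely act as transients. Subjects share centers but
#' differ in epoch order, epoch lengths and noise.
#'
#' @param cfg a [switchingConfig()].
#' @param nSubjects number of subjects.
#' @return list with \code{trajectories} (list of normalized
#'   \linkS4class{StateTrajectory}), \code{labels} (list of per-sample
#'   ground-truth integer labels, 0 = transient) and \code{centers}
#'   (nStates x M matrix).
#' @examples
#' ens <- generateSwitchingEnsemble(
#'     switchingConfig(nModules = 10, T = 300, seed = 7), nSubjects = 2)
#' table(ens$labels[[1]])
#' @export
generateSwitchingEnsemble <- function(cfg, nSubjects = 1L) {
    stopifnot(inherits(cfg, "SwitchingConfig"))
    set.seed(cfg$seed)
    centers <- .drawCenters(cfg$nStates, cfg$nModules, cfg$minCenterAngle)
    nEpochs <- ceiling(2 * cfg$T / (cfg$meanDwell + cfg$transientLen)) +
        cfg$nStates
    trajectories <- vector("list", nSubjects)
    labels <- vector("list", nSubjects)
    for (sb in seq_len(nSubjects)) {
        order <- .epochOrder(cfg$nStates, nEpochs)
        rows <- matrix(0, cfg$T, cfg$nModules)
        lab <- integer(cfg$T)
        t <- 0L
        for (e in seq_along(order)) {
            if (t >= cfg$T) break
            state <- order[e]
            dwell <- rgeom(1L, 1 / max(cfg$meanDwell, 1L)) + 1L
            for (k in seq_len(dwell)) {
                if (t >= cfg$T) break
                t <- t + 1L
                rows[t, ] <- .unitize(centers[state, ] +
                    rnorm(cfg$nModules, sd = cfg$noiseSigma))
                lab[t] <- state
            }
            nxt <- if (e < length(order)) order[e + 1L] else NA_integer_
            if (!is.na(nxt) && cfg$transientLen > 0L && t < cfg$T) {
                for (k in seq_len(cfg$transientLen)) {
                    if (t >= cfg$T) break
                    t <- t + 1L
                    f <- k / (cfg$transientLen + 1)
                    base <- .slerp(centers[state, ], centers[nxt, ], f)
                    defl <- cfg$transitJitter * sin(pi * f) *
                        .unitize(rnorm(cfg$nModules))
                    rows[t, ] <- .unitize(base + defl +
                        rnorm(cfg$nModules, sd = cfg$noiseSigma))
                    lab[t] <- 0L
                }
            }
        }
        trajectories[[sb]] <- stateTrajectory(rows, normalized = TRUE)
        labels[[sb]] <- lab
    }
    names(trajectories) <- names(labels) <-
        sprintf("subject%02d", seq_len(nSubjects))
    list(trajectories = trajectories, labels = labels, centers = centers)
}
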