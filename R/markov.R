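# Markov transition model estimation and utility-based ball-size selection.

#' Estimate the Markov transition matrix of a segmentation
#'
#' Counts label bigrams s[t] -> s[t + 1] and normalizes per origin state,
#' giving the column-stochastic conditional probabilities p_ij of moving
#' from state j into state i in one sampling step. States are indexed with
#' the transient (0) first, when present, followed by the metastable
#' symbols in order of first appearance. A state observed only at the
#' final time point has no outgoing bigram; its column is set to the
#' absorbing column p_jj = 1, which preserves stochasticity without
#' inventing transitions.
#'
#' @param seg a relabeled \linkS4class{RecurrenceSegmentation}, or an
#'   integer symbol vector (0 = transient), with at least 2 time points.
#' @return a \linkS4class{TransitionModel}.
#' @examples
#' tm <- estimateTransitionMatrix(c(1L, 0L, 1L, 0L, 1L))
#' transitionProbs(tm)
#' @export
estimateTransitionMatrix <- function(seg) {
    s <- if (is(seg, "RecurrenceSegmentation")) symbolSequence(seg)
         else as.integer(seg)
    if (length(s) < 2L)
        stop("estimateTransitionMatrix: need at least 2 time points")
    pos <- unique(s[s > 0L])               # order of first appearance
    states <- if (any(s == 0L)) c(0L, pos) else pos
    n <- length(states)
    idx <- match(s, states)
    counts <- matrix(0, n, n)
    from <- idx[-length(idx)]
    to <- idx[-1L]
    for (k in seq_along(from))
        counts[to[k], from[k]] <- counts[to[k], from[k]] + 1
    tot <- colSums(counts)
    probs <- counts
    for (j in seq_len(n)) {
        if (tot[j] == 0) probs[j, j] <- 1     # absorbing-column convention
        else probs[, j] <- counts[, j] / tot[j]
    }
    new("TransitionModel", probs = probs, states = states)
}

# Normalized entropy of a renormalized transition distribution. 'n' is the
# total number of states including the transient. Conventions: an empty
# distribution (all-zero denominator) contributes 0; with a single
# metastable state (n == 2) a nonempty one-outcome distribution is
# trivially uniform and contributes 1.
.normalizedEntropy <- function(v, n) {
    tot <- sum(v)
    if (tot <= 0) return(0)
    if (n == 2L) return(1)
    p <- v / tot
    p <- p[p > 0]
    -sum(p * log(p)) / log(n - 1)
}

#' Markov utility of a transition model
#'
#' Scores a transition matrix by
#' \code{u = (trace(P) + h_r + h_c) / (n + 2)}, where n is the number of
#' states including the distinguished transient and h_r, h_c are the
#' log(n - 1)-normalized entropies of the renormalized transition
#' probabilities out of the metastable states into the transient (the
#' transient row) and out of the transient into the metastable states (the
#' transient column). Large traces reward dwelling (metastability); large
#' entropies reward uniformly distributed excursions through the
#' transient, per a maximum-entropy assumption on the transition regime.
#' The value always lies in [0, 1].
#'
#' Conventions for degenerate cases: an empty renormalization denominator
#' contributes entropy 0; n = 2 with a nonempty (one-outcome) distribution
#' contributes 1; when the transient state is absent from the model the
#' conceptual transient row/column are empty and n is the number of
#' metastable states + 1; an all-transient segmentation (n = 1) scores
#' \code{p_00 / 3}.
#'
#' @param tm a \linkS4class{TransitionModel}.
#' @return utility value in [0, 1].
#' @examples
#' markovUtility(estimateTransitionMatrix(c(1L, 0L, 1L, 0L, 1L)))  # 0.5
#' @export
markovUtility <- function(tm) {
    P <- transitionProbs(tm)
    states <- modelStates(tm)
    if (any(abs(colSums(P) - 1) > 1e-8))
        stop("markovUtility: transition matrix columns must sum to 1")
    hasTransient <- 0L %in% states
    m <- nrow(P)
    n <- if (hasTransient) m else m + 1L
    if (n == 1L) return(P[1L, 1L] / 3)
    tr <- sum(diag(P))
    if (hasTransient) {
        t0 <- match(0L, states)
        row0 <- P[t0, -t0]     # p_0j: metastable j -> transient
        col0 <- P[-t0, t0]     # p_i0: transient -> metastable i
        hr <- .normalizedEntropy(row0, n)
        hc <- .normalizedEntropy(col0, n)
    } else {
        hr <- 0
        hc <- 0
    }
    (tr + hr + hc) / (n + 2)
}

#' Number of metastable states of a segmentation
#'
#' The segmentation complexity n - 1: the number of distinct positive
#' symbols (the transient does not count).
#'
#' @param seg a relabeled \linkS4class{RecurrenceSegmentation} or integer
#'   symbol vector.
#' @return nonnegative integer.
#' @export
segmentationComplexity <- function(seg) {
    s <- if (is(seg, "RecurrenceSegmentation")) symbolSequence(seg)
         else as.integer(seg)
    length(unique(s[s > 0L]))
}

#' Ball-size grid from the pairwise distance distribution
#'
#' The default ("linear") grid spans 50 evenly spaced values between the
#' 5th and 95th percentile of the off-diagonal pairwise cosine distances.
#' The "log" grid spaces the same number of values evenly on a log scale
#' between the 1st and 95th percentile, resolving the short-distance end;
#' appropriate for densely sampled deterministic flows whose recurrence
#' structure spans several orders of magnitude.
#'
#' @param traj a normalized \linkS4class{StateTrajectory} or matrix.
#' @param n number of grid points.
#' @param scale "linear" or "log".
#' @return increasing numeric vector of positive ball sizes.
#' @export
epsilonGrid <- function(traj, n = 50L, scale = c("linear", "log")) {
    scale <- match.arg(scale)
    d <- cosineDistanceMatrix(traj)
    offd <- d[upper.tri(d)]
    if (scale == "linear") {
        qs <- quantile(offd, c(0.05, 0.95), names = FALSE)
        g <- seq(qs[1], qs[2], length.out = n)
    } else {
        qs <- quantile(offd, c(0.01, 0.95), names = FALSE)
        lo <- max(qs[1], 1e-8)
        hi <- max(qs[2], lo * 10)
        g <- exp(seq(log(lo), log(hi), length.out = n))
    }
    unique(pmax(g, 1e-8))
}

#' Optimize the recurrence ball size by Markov utility
#'
#' For every ball size on the grid the trajectory is segmented with the
#' recurrence grammar, transients are relabeled, the transition matrix is
#' estimated and scored with [markovUtility()]. The selected
#' \code{bestEpsilon} is the smallest grid value attaining the maximal
#' utility (ties break toward finer partitions), entailing a maximally
#' metastable Markov state model.
#'
#' @param traj a normalized \linkS4class{StateTrajectory} (or matrix with
#'   unit-norm rows).
#' @param grid strictly increasing positive ball sizes, or NULL for the
#'   automatic linear percentile grid of [epsilonGrid()].
#' @param minDwell minimal class size passed to [relabelTransients()].
#' @return a \linkS4class{UtilityCurve}.
#' @export
optimizeEpsilon <- function(traj, grid = NULL, minDwell = 2L) {
    d <- cosineDistanceMatrix(traj)
    nT <- nrow(d)
    if (is.null(grid)) {
        offd <- d[upper.tri(d)]
        qs <- quantile(offd, c(0.05, 0.95), names = FALSE)
        grid <- unique(pmax(seq(qs[1], qs[2], length.out = 50L), 1e-8))
    } else {
        if (length(grid) < 1L)
            stop("optimizeEpsilon: empty ball-size grid")
        if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE))
            stop("optimizeEpsilon: grid must be strictly increasing and positive")
    }
    ut <- upper.tri(d)
    distUpper <- d[ut]
    n <- nrow(d)
    idx <- which(ut)
    colIdx <- ((idx - 1L) %/% n) + 1L
    rowIdx <- ((idx - 1L) %% n) + 1L
    utilities <- numeric(length(grid))
    complexities <- integer(length(grid))
    segs <- vector("list", length(grid))
    for (g in seq_along(grid)) {
        s <- .segmentFromDistances(distUpper, colIdx, rowIdx, nT, grid[g])
        seg <- relabelTransients(
            new("RecurrenceSegmentation", symbols = as.integer(s),
                relabeled = FALSE, epsilon = grid[g]),
            minDwell = minDwell)
        utilities[g] <- markovUtility(estimateTransitionMatrix(seg))
        complexities[g] <- segmentationComplexity(seg)
        segs[[g]] <- seg
    }
    best <- which.max(utilities)     # first (= smallest epsilon) maximum
    new("UtilityCurve", epsilons = as.numeric(grid), utilities = utilities,
        complexities = complexities, bestEpsilon = grid[best],
        bestSegmentation = segs[[best]])
}
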