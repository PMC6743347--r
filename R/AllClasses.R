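# S4 containers for the recurrence structure analysis pipeline.

#' StateTrajectory: a discretely sampled multivariate trajectory
#'
#' Rows are time points, columns are modules (observables). The
#' \code{normalized} flag records whether every row has been scaled to unit
#' Euclidean norm, the representation on which cosine-distance recurrence is
#' defined.
#'
#' @slot values numeric matrix, T x M, all entries finite, T >= 2, M >= 1.
#' @slot sampleInterval sampling interval in seconds (length-0 or length-1;
#'   metadata only).
#' @slot normalized logical scalar; when TRUE every row has unit norm.
#'
#' @exportClass StateTrajectory
setClass("StateTrajectory",
    representation(values = "matrix", sampleInterval = "numeric",
                   normalized = "logical"),
    prototype(sampleInterval = numeric(0), normalized = FALSE))

setValidity("StateTrajectory", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("'values' must be a numeric matrix")
    if (nrow(v) < 2L) return("a trajectory needs at least 2 time points")
    if (ncol(v) < 1L) return("a trajectory needs at least 1 module")
    if (!all(is.finite(v))) return("'values' contains non-finite entries")
    if (length(object@sampleInterval) > 1L)
        return("'sampleInterval' must have length 0 or 1")
    if (length(object@normalized) != 1L)
        return("'normalized' must be a logical scalar")
    if (isTRUE(object@normalized)) {
        norms <- sqrt(rowSums(v^2))
        if (any(abs(norms - 1) > 1e-8))
            return("rows of a normalized trajectory must have unit norm")
    }
    TRUE
})

#' Construct a StateTrajectory
#'
#' @param values numeric matrix (rows = time points, columns = modules).
#' @param sampleInterval optional sampling interval in seconds.
#' @param normalized logical; assert that rows are unit-norm.
#' @return a \linkS4class{StateTrajectory}.
#' @examples
#' traj <- stateTrajectory(matrix(rnorm(20), 10, 2))
#' nTimes(traj)
#' @export
stateTrajectory <- function(values, sampleInterval = numeric(0),
                            normalized = FALSE) {
    if (is.data.frame(values)) values <- as.matrix(values)
    if (!is.matrix(values)) values <- matrix(values, ncol = 1L)
    storage.mode(values) <- "double"
    new("StateTrajectory", values = values,
        sampleInterval = as.numeric(sampleInterval),
        normalized = isTRUE(normalized))
}

#' @describeIn stateTrajectory the T x M value matrix.
#' @param x a \linkS4class{StateTrajectory}.
#' @export
trajValues <- function(x) {
    if (is(x, "StateTrajectory")) x@values else as.matrix(x)
}

#' @describeIn stateTrajectory number of time points.
#' @export
nTimes <- function(x) nrow(trajValues(x))

#' @describeIn stateTrajectory number of modules (columns).
#' @export
nModules <- function(x) ncol(trajValues(x))

#' @describeIn stateTrajectory TRUE when rows are unit-normalized.
#' @export
isNormalized <- function(x) is(x, "StateTrajectory") && isTRUE(x@normalized)

#' RecurrencePlot: binary time-by-time recurrence matrix
#'
#' Entry (i, j) is TRUE when the cosine distance between states i and j is
#' strictly below the ball size epsilon. The matrix is symmetric with a unit
#' diagonal.
#'
#' @slot matrix logical T x T matrix.
#' @slot epsilon positive recurrence ball size.
#'
#' @exportClass RecurrencePlot
setClass("RecurrencePlot",
    representation(matrix = "matrix", epsilon = "numeric"))

setValidity("RecurrencePlot", function(object) {
    m <- object@matrix
    if (!is.logical(m)) return("'matrix' must be logical")
    if (nrow(m) != ncol(m)) return("'matrix' must be square")
    if (length(object@epsilon) != 1L || !is.finite(object@epsilon) ||
        object@epsilon <= 0)
        return("'epsilon' must be a positive scalar")
    if (!all(diag(m))) return("recurrence plot diagonal must be all TRUE")
    if (!identical(m, t(m))) return("recurrence plot must be symmetric")
    TRUE
})

#' @describeIn recurrencePlot the logical recurrence matrix.
#' @export
rpMatrix <- function(x) x@matrix

#' @describeIn recurrencePlot the ball size used to build the plot.
#' @export
rpEpsilon <- function(x) x@epsilon

#' RecurrenceSegmentation: symbolic sequence of metastable states
#'
#' One nonnegative integer symbol per time point. Before transient
#' relabeling each symbol is the minimal 1-based time index of its
#' recurrence class (so \code{symbol[t] <= t}); after relabeling, 0 marks
#' transients and every surviving positive class has at least
#' \code{minDwell} members.
#'
#' @slot symbols integer vector of per-time-point labels.
#' @slot relabeled logical; TRUE once transients have been relabeled to 0.
#' @slot minDwell minimal class size used for relabeling (NA before).
#' @slot epsilon ball size the segmentation came from (NA when unknown).
#'
#' @exportClass RecurrenceSegmentation
setClass("RecurrenceSegmentation",
    representation(symbols = "integer", relabeled = "logical",
                   minDwell = "integer", epsilon = "numeric"),
    prototype(relabeled = FALSE, minDwell = NA_integer_,
              epsilon = NA_real_))

setValidity("RecurrenceSegmentation", function(object) {
    s <- object@symbols
    if (length(s) < 1L) return("empty symbol sequence")
    if (any(is.na(s)) || any(s < 0L)) return("symbols must be >= 0")
    if (!object@relabeled) {
        if (any(s == 0L)) return("0 labels only appear after relabeling")
        if (any(s > seq_along(s)))
            return("grammar symbols must satisfy symbol[t] <= t")
    } else if (!is.na(object@minDwell)) {
        counts <- table(s[s > 0L])
        if (length(counts) && any(counts < object@minDwell))
            return("a surviving class is smaller than minDwell")
    }
    TRUE
})

#' @describeIn recurrenceSegment integer symbol per time point.
#' @export
symbolSequence <- function(x) x@symbols

#' @describeIn recurrenceSegment sorted distinct positive symbols present.
#' @export
segmentAlphabet <- function(x) sort(unique(x@symbols[x@symbols > 0L]))

#' @describeIn recurrenceSegment number of states n including the
#'   distinguished transient (number of metastable classes + 1).
#' @export
nStates <- function(x) length(segmentAlphabet(x)) + 1L

#' MetastablePartition: state clouds plus transient time points
#'
#' The clouds and the transient set partition \code{1..T}.
#'
#' @slot clouds list of \linkS4class{StateCloud} objects, one per
#'   metastable state, ordered by symbol.
#' @slot transientTimes integer time indices labeled transient.
#' @slot nTime total number of time points.
#'
#' @exportClass MetastablePartition
setClass("MetastablePartition",
    representation(clouds = "list", transientTimes = "integer",
                   nTime = "integer"))

setValidity("MetastablePartition", function(object) {
    idx <- unlist(lapply(object@clouds, function(cl) cl@timeIndices))
    all_idx <- c(idx, object@transientTimes)
    if (anyDuplicated(all_idx))
        return("classes and transients must be disjoint")
    if (!setequal(all_idx, seq_len(object@nTime)))
        return("classes and transients must cover 1..T")
    TRUE
})

#' StateCloud: the states of one metastable class
#'
#' @slot points numeric matrix of unit-norm state vectors (rows).
#' @slot timeIndices integer time points the rows came from.
#' @slot subject subject identifier.
#' @slot symbol positive integer subject-level state label.
#'
#' @exportClass StateCloud
setClass("StateCloud",
    representation(points = "matrix", timeIndices = "integer",
                   subject = "character", symbol = "integer"))

setValidity("StateCloud", function(object) {
    p <- object@points
    if (nrow(p) < 1L) return("a state cloud cannot be empty")
    if (nrow(p) != length(object@timeIndices))
        return("'timeIndices' must match the number of points")
    norms <- sqrt(rowSums(p^2))
    if (any(abs(norms - 1) > 1e-6))
        return("state cloud points must be unit-norm")
    if (length(object@symbol) != 1L || object@symbol < 1L)
        return("'symbol' must be a positive integer")
    TRUE
})

#' @describeIn extractStates matrix of points of one cloud.
#' @param x a \linkS4class{StateCloud}.
#' @export
cloudPoints <- function(x) x@points

#' @describeIn extractStates time indices contributing to one cloud.
#' @export
cloudTimes <- function(x) x@timeIndices

#' TransitionModel: column-stochastic Markov transition matrix
#'
#' \code{probs[i, j]} is the estimated probability of moving from state
#' \code{states[j]} at time t to state \code{states[i]} at time t + 1.
#' State 0 is the distinguished transient; metastable symbols follow in
#' order of first appearance in the segmentation.
#'
#' @slot probs numeric n x n column-stochastic matrix.
#' @slot states integer symbols indexing rows/columns (0 = transient).
#'
#' @exportClass TransitionModel
setClass("TransitionModel",
    representation(probs = "matrix", states = "integer"))

setValidity("TransitionModel", function(object) {
    P <- object@probs
    if (nrow(P) != ncol(P)) return("'probs' must be square")
    if (nrow(P) != length(object@states))
        return("'states' must index the matrix")
    if (any(P < -1e-12) || any(P > 1 + 1e-12))
        return("probabilities must lie in [0, 1]")
    if (any(abs(colSums(P) - 1) > 1e-9))
        return("columns must sum to 1")
    TRUE
})

#' @describeIn estimateTransitionMatrix the column-stochastic matrix.
#' @export
transitionProbs <- function(x) x@probs

#' @describeIn estimateTransitionMatrix symbols indexing the matrix
#'   (0 = transient).
#' @export
modelStates <- function(x) x@states

#' UtilityCurve: Markov utility over a ball-size grid
#'
#' @slot epsilons increasing grid of ball sizes.
#' @slot utilities utility u(epsilon) in [0, 1] per grid value.
#' @slot complexities number of metastable states (n - 1) per grid value.
#' @slot bestEpsilon smallest grid value attaining the maximal utility.
#' @slot bestSegmentation relabeled segmentation at \code{bestEpsilon}.
#'
#' @exportClass UtilityCurve
setClass("UtilityCurve",
    representation(epsilons = "numeric", utilities = "numeric",
                   complexities = "integer", bestEpsilon = "numeric",
                   bestSegmentation = "RecurrenceSegmentation"))

setValidity("UtilityCurve", function(object) {
    if (length(object@epsilons) != length(object@utilities) ||
        length(object@epsilons) != length(object@complexities))
        return("grid, utilities and complexities must have equal length")
    if (is.unsorted(object@epsilons, strictly = TRUE))
        return("'epsilons' must be strictly increasing")
    if (any(object@utilities < -1e-9 | object@utilities > 1 + 1e-9))
        return("utilities must lie in [0, 1]")
    u <- object@utilities[match(object@bestEpsilon, object@epsilons)]
    if (is.na(u) || abs(u - max(object@utilities)) > 1e-12)
        return("'bestEpsilon' must attain the maximal utility")
    TRUE
})

#' @describeIn optimizeEpsilon grid, utility and complexity as a data.frame.
#' @export
utilityTable <- function(x) {
    data.frame(epsilon = x@epsilons, utility = x@utilities,
               complexity = x@complexities)
}

#' @describeIn optimizeEpsilon the selected ball size.
#' @export
bestEpsilon <- function(x) x@bestEpsilon

#' @describeIn optimizeEpsilon the relabeled segmentation at the selected
#'   ball size.
#' @export
bestSegmentation <- function(x) x@bestSegmentation

#' HausdorffMatrix: pairwise Hausdorff distances between pooled clouds
#'
#' @slot dist symmetric nonnegative P x P matrix with zero diagonal.
#' @slot index data.frame with columns \code{subject} and \code{symbol}
#'   identifying the pooled clouds in matrix order.
#'
#' @exportClass HausdorffMatrix
setClass("HausdorffMatrix",
    representation(dist = "matrix", index = "data.frame"))

setValidity("HausdorffMatrix", function(object) {
    D <- object@dist
    if (nrow(D) != ncol(D)) return("'dist' must be square")
    if (nrow(D) != nrow(object@index))
        return("'index' must describe every row of 'dist'")
    if (any(D < 0)) return("distances must be nonnegative")
    if (any(abs(diag(D)) > 1e-12)) return("diagonal must be zero")
    if (max(abs(D - t(D))) > 1e-12) return("'dist' must be symmetric")
    TRUE
})

#' @describeIn hausdorffMatrix the P x P distance matrix.
#' @export
hausdorffValues <- function(x) x@dist

#' @describeIn hausdorffMatrix pooled (subject, symbol) index.
#' @export
hausdorffIndex <- function(x) x@index

#' EnsembleClustering: Hausdorff clustering of pooled state clouds
#'
#' @slot labels data.frame with columns \code{subject}, \code{symbol} and
#'   \code{cluster}; cluster ids are minimal pooled indices.
#' @slot theta distance threshold used.
#' @slot nClusters number of clusters.
#'
#' @exportClass EnsembleClustering
setClass("EnsembleClustering",
    representation(labels = "data.frame", theta = "numeric",
                   nClusters = "integer"))

setValidity("EnsembleClustering", function(object) {
    lab <- object@labels
    if (!all(c("subject", "symbol", "cluster") %in% names(lab)))
        return("'labels' needs subject, symbol and cluster columns")
    if (object@nClusters != length(unique(lab$cluster)))
        return("'nClusters' does not match the labels")
    TRUE
})

#' @describeIn clusterStates (subject, symbol) -> cluster table.
#' @export
clusterLabels <- function(x) x@labels

#' @describeIn clusterStates number of ensemble clusters.
#' @export
nClusters <- function(x) x@nClusters

#' MixingMatrix: linear map from module space to region space
#'
#' @slot weights K x M numeric matrix (regions by modules).
#' @slot regionLabels K unique region names.
#' @slot space one of "AAL", "RSN", "custom".
#'
#' @exportClass MixingMatrix
setClass("MixingMatrix",
    representation(weights = "matrix", regionLabels = "character",
                   space = "character"))

setValidity("MixingMatrix", function(object) {
    if (nrow(object@weights) < 1L) return("need at least one region")
    if (!all(is.finite(object@weights)))
        return("'weights' must be finite")
    if (length(object@regionLabels) != nrow(object@weights))
        return("'regionLabels' must name every row")
    if (anyDuplicated(object@regionLabels))
        return("region labels must be unique")
    if (!object@space %in% c("AAL", "RSN", "custom"))
        return("'space' must be AAL, RSN or custom")
    TRUE
})

#' Construct a MixingMatrix
#'
#' @param weights K x M numeric matrix mapping M modules to K regions.
#' @param regionLabels character vector of K unique region names; defaults
#'   to the row names of \code{weights}.
#' @param space region space tag, one of "AAL", "RSN", "custom".
#' @return a \linkS4class{MixingMatrix}.
#' @export
mixingMatrix <- function(weights, regionLabels = rownames(weights),
                         space = "custom") {
    weights <- as.matrix(weights)
    storage.mode(weights) <- "double"
    if (is.null(regionLabels))
        regionLabels <- sprintf("region_%02d", seq_len(nrow(weights)))
    rownames(weights) <- regionLabels
    new("MixingMatrix", weights = weights,
        regionLabels = as.character(regionLabels), space = space)
}

#' @describeIn mixingMatrix the K x M weight matrix.
#' @param x a \linkS4class{MixingMatrix}.
#' @export
mixingWeights <- function(x) x@weights

#' @describeIn mixingMatrix the K region labels.
#' @export
regionLabels <- function(x) x@regionLabels
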