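# Recurrence plots and recurrence-grammar segmentation.

#' Build a recurrence plot
#'
#' Entry (i, j) is TRUE exactly when the cosine distance between the states
#' at times i and j is strictly below \code{epsilon}. The diagonal is TRUE
#' for any positive ball size and the matrix is symmetric.
#'
#' @param traj a normalized \linkS4class{StateTrajectory} (or matrix with
#'   unit-norm rows).
#' @param epsilon positive ball size.
#' @return a \linkS4class{RecurrencePlot}.
#' @examples
#' traj <- normalizeTrajectory(matrix(rnorm(30), 10, 3), "unit")
#' rp <- recurrencePlot(traj, 0.2)
#' @export
recurrencePlot <- function(traj, epsilon) {
    if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
        stop("recurrencePlot: 'epsilon' must be a positive scalar")
    d <- cosineDistanceMatrix(traj)
    m <- d < epsilon
    diag(m) <- TRUE
    new("RecurrencePlot", matrix = m, epsilon = as.numeric(epsilon))
}

# Recurrent pairs (i > j) of a recurrence matrix as an edge list.
.recurrentPairs <- function(m) {
    idx <- which(m & upper.tri(m))
    n <- nrow(m)
    j <- ((idx - 1L) %/% n) + 1L   # column (later time)
    i <- ((idx - 1L) %% n) + 1L    # row (earlier time)
    list(i = j, j = i)             # i > j convention: first = larger index
}

#' Segment a recurrence plot with the recurrence grammar
#'
#' Starting from the sequence of 1-based time indices s[t] = t, every
#' recurrent pair i > j induces a rewriting rule i -> j replacing the
#' larger symbol by the smaller one; rules derived from shared recurrences
#' chain further down. The grammar is applied repeatedly until a fixed
#' point, at which every symbol equals the minimal time index of its
#' connected component in the recurrence graph.
#'
#' @param rp a \linkS4class{RecurrencePlot}.
#' @return an unrelabeled \linkS4class{RecurrenceSegmentation}.
#' @seealso [relabelTransients()] to map rare classes to the transient
#'   label 0, [applyRecurrenceGrammar()] for single-pass application.
#' @export
recurrenceSegment <- function(rp) {
    m <- rpMatrix(rp)
    pairs <- .recurrentPairs(m)
    s <- .grammar_iterate(seq_len(nrow(m)), pairs$i, pairs$j, -1L)
    new("RecurrenceSegmentation", symbols = as.integer(s),
        relabeled = FALSE, epsilon = rpEpsilon(rp))
}

#' Apply the recurrence grammar a fixed number of passes
#'
#' One pass applies every rewriting rule of the recurrence plot once
#' (synchronously) to the given symbol sequence. Exposed mainly to verify
#' grammar properties such as idempotence at the fixed point.
#'
#' @param symbols integer symbol sequence (length T).
#' @param rp a \linkS4class{RecurrencePlot} with T time points.
#' @param passes number of passes, or -1 to iterate to the fixed point.
#' @return the rewritten integer symbol sequence.
#' @export
applyRecurrenceGrammar <- function(symbols, rp, passes = 1L) {
    m <- rpMatrix(rp)
    if (length(symbols) != nrow(m))
        stop("applyRecurrenceGrammar: sequence length must match the plot")
    pairs <- .recurrentPairs(m)
    as.integer(.grammar_iterate(as.integer(symbols), pairs$i, pairs$j,
                                as.integer(passes)))
}

# Grammar fixed point straight from a distance matrix; avoids building a
# T x T logical copy per epsilon during grid optimization.
.segmentFromDistances <- function(distUpper, pairsI, pairsJ, nT, epsilon) {
    keep <- distUpper < epsilon
    .grammar_iterate(seq_len(nT), pairsI[keep], pairsJ[keep], -1L)
}

#' Relabel rare recurrence classes as transients
#'
#' Classes with fewer than \code{minDwell} members are not metastable --
#' the trajectory never dwells there -- and are relabeled 0 (the
#' distinguished transient). Surviving classes keep their minimal-index
#' labels. With the resulting segmentation, \code{nStates()} returns
#' n = number of surviving classes + 1 (the transient counts as one state).
#'
#' @param seg a \linkS4class{RecurrenceSegmentation} (a grammar fixed
#'   point).
#' @param minDwell positive integer: minimal class size that counts as
#'   metastable (default 2, i.e. non-recurrent singletons are transient).
#' @return a relabeled \linkS4class{RecurrenceSegmentation}.
#' @examples
#' seg <- new("RecurrenceSegmentation",
#'            symbols = c(1L, 2L, 1L, 4L, 1L), relabeled = FALSE)
#' symbolSequence(relabelTransients(seg))
#' @export
relabelTransients <- function(seg, minDwell = 2L) {
    if (!is.numeric(minDwell) || length(minDwell) != 1L || minDwell < 1)
        stop("relabelTransients: 'minDwell' must be a positive integer")
    minDwell <- as.integer(minDwell)
    s <- symbolSequence(seg)
    counts <- table(s)
    rare <- as.integer(names(counts)[counts < minDwell])
    s[s %in% rare] <- 0L
    new("RecurrenceSegmentation", symbols = s, relabeled = TRUE,
        minDwell = minDwell, epsilon = seg@epsilon)
}

#' Extract metastable state clouds from a segmentation
#'
#' For each positive symbol k the cloud collects exactly the trajectory
#' rows whose label is k; time points labeled 0 form the transient set.
#' Clouds are mutually disjoint and, together with the transients, cover
#' all time points.
#'
#' @param traj the normalized \linkS4class{StateTrajectory} the
#'   segmentation came from.
#' @param seg a \linkS4class{RecurrenceSegmentation} of matching length.
#' @param subject subject identifier attached to the clouds.
#' @return a \linkS4class{MetastablePartition}.
#' @export
extractStates <- function(traj, seg, subject = "subject1") {
    v <- trajValues(traj)
    s <- symbolSequence(seg)
    if (nrow(v) != length(s))
        stop("extractStates: trajectory and segmentation lengths differ")
    alphabet <- segmentAlphabet(seg)
    clouds <- lapply(alphabet, function(k) {
        idx <- which(s == k)
        new("StateCloud", points = v[idx, , drop = FALSE],
            timeIndices = idx, subject = subject, symbol = as.integer(k))
    })
    new("MetastablePartition", clouds = clouds,
        transientTimes = which(s == 0L), nTime = length(s))
}
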