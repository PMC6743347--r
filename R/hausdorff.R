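# Ensemble analysis: Hausdorff distances between pooled state clouds and
# grammar-based clustering across subjects.

.cloudMatrix <- function(x) {
    if (is(x, "StateCloud")) cloudPoints(x) else as.matrix(x)
}

#' Hausdorff distance between two state clouds
#'
#' The maximum over both directions of the max-min cosine distance: for
#' every point of one cloud take its distance to the nearest point of the
#' other cloud, and keep the worst case. Zero exactly when the two point
#' sets coincide; symmetric.
#'
#' @param A,B \linkS4class{StateCloud} objects or matrices of unit-norm
#'   rows, in the same dimension.
#' @return nonnegative scalar.
#' @examples
#' hausdorffDistance(rbind(c(1, 0), c(0, 1)), rbind(c(1, 0)))  # 1
#' @export
hausdorffDistance <- function(A, B) {
    a <- .cloudMatrix(A)
    b <- .cloudMatrix(B)
    if (nrow(a) < 1L || nrow(b) < 1L)
        stop("hausdorffDistance: empty state cloud")
    if (ncol(a) != ncol(b))
        stop("hausdorffDistance: clouds live in different dimensions")
    cross <- 1 - tcrossprod(a, b)        # |A| x |B| cosine distances
    max(max(apply(cross, 1L, min)), max(apply(cross, 2L, min)))
}

#' Pairwise Hausdorff distances between pooled state clouds
#'
#' @param clouds list of \linkS4class{StateCloud} objects pooled over
#'   subjects.
#' @return a \linkS4class{HausdorffMatrix}; each pair is computed once so
#'   symmetry is exact.
#' @export
hausdorffMatrix <- function(clouds) {
    if (length(clouds) < 1L)
        stop("hausdorffMatrix: need at least one cloud")
    dims <- vapply(clouds, function(cl) ncol(.cloudMatrix(cl)), integer(1))
    if (length(unique(dims)) != 1L)
        stop("hausdorffMatrix: clouds live in different dimensions")
    p <- length(clouds)
    D <- matrix(0, p, p)
    if (p > 1L) {
        for (i in seq_len(p - 1L)) {
            for (j in seq(i + 1L, p)) {
                D[i, j] <- D[j, i] <- hausdorffDistance(clouds[[i]],
                                                        clouds[[j]])
            }
        }
    }
    index <- data.frame(
        subject = vapply(clouds, function(cl)
            if (is(cl, "StateCloud")) cl@subject else NA_character_,
            character(1)),
        symbol = vapply(clouds, function(cl)
            if (is(cl, "StateCloud")) cl@symbol else NA_integer_,
            integer(1)),
        stringsAsFactors = FALSE)
    new("HausdorffMatrix", dist = D, index = index)
}

#' Cluster pooled state clouds by thresholded Hausdorff distance
#'
#' Thresholding the distance matrix at theta (strictly, D < theta) yields
#' a binary recurrence matrix over pooled cloud indices; the recurrence
#' grammar applied to it merges clouds into ensemble clusters, each
#' labeled by its minimal pooled index.
#'
#' @param D a \linkS4class{HausdorffMatrix}.
#' @param theta positive distance threshold (the study default is 0.8).
#' @return an \linkS4class{EnsembleClustering}.
#' @export
clusterStates <- function(D, theta = 0.8) {
    if (!is.numeric(theta) || length(theta) != 1L || theta <= 0)
        stop("clusterStates: 'theta' must be a positive scalar")
    dm <- hausdorffValues(D)
    q <- dm < theta
    diag(q) <- TRUE
    pairs <- .recurrentPairs(q)
    lab <- .grammar_iterate(seq_len(nrow(q)), pairs$i, pairs$j, -1L)
    labels <- hausdorffIndex(D)
    labels$cluster <- as.integer(lab)
    new("EnsembleClustering", labels = labels, theta = as.numeric(theta),
        nClusters = length(unique(lab)))
}

#' Coverage of the subject ensemble by ensemble clusters
#'
#' Reports, per cluster, how many clouds it absorbed and how many distinct
#' subjects contribute to it, and per subject how many clusters it reaches.
#' Full coverage means every subject contributes to every cluster -- the
#' condition under which a minimal set of metastable states covers the
#' whole ensemble.
#'
#' @param clustering an \linkS4class{EnsembleClustering}.
#' @param subjects optional character vector of all subject ids (defaults
#'   to the subjects present in the clustering).
#' @return list with elements \code{clusterTable} (cluster, nClouds,
#'   nSubjects), \code{subjectTable} (subject, nClusters) and the logical
#'   \code{fullCoverage}.
#' @export
coverageReport <- function(clustering, subjects = NULL) {
    lab <- clusterLabels(clustering)
    if (is.null(subjects)) subjects <- unique(lab$subject)
    clusters <- sort(unique(lab$cluster))
    clusterTable <- data.frame(
        cluster = clusters,
        nClouds = vapply(clusters, function(k)
            sum(lab$cluster == k), integer(1)),
        nSubjects = vapply(clusters, function(k)
            length(unique(lab$subject[lab$cluster == k])), integer(1)))
    subjectTable <- data.frame(
        subject = subjects,
        nClusters = vapply(subjects, function(sb)
            length(unique(lab$cluster[lab$subject == sb])), integer(1)))
    full <- all(clusterTable$nSubjects == length(subjects))
    list(clusterTable = clusterTable, subjectTable = subjectTable,
         fullCoverage = full)
}

#' Threshold search for the finest full-coverage clustering
#'
#' Evaluates a theta grid and reports the number of clusters and coverage
#' at each value. The suggested threshold is the smallest grid value at
#' which every subject contributes to every cluster: the finest
#' clustering that still covers the whole ensemble. (The cluster count is
#' non-increasing in theta, and a large enough theta always covers the
#' ensemble with a single merged cluster, so minimizing the cluster count
#' directly would be degenerate.)
#'
#' @param D a \linkS4class{HausdorffMatrix}.
#' @param thetaGrid increasing positive thresholds to scan.
#' @return list with a per-theta \code{table} (theta, nClusters,
#'   fullCoverage) and \code{theta}, the suggested threshold (NA when no
#'   grid value achieves full coverage).
#' @export
selectTheta <- function(D, thetaGrid = seq(0.1, 1.5, by = 0.05)) {
    if (any(thetaGrid <= 0))
        stop("selectTheta: thresholds must be positive")
    rows <- lapply(thetaGrid, function(th) {
        cl <- clusterStates(D, th)
        cov <- coverageReport(cl)
        data.frame(theta = th, nClusters = nClusters(cl),
                   fullCoverage = cov$fullCoverage)
    })
    tab <- do.call(rbind, rows)
    ok <- tab[tab$fullCoverage, , drop = FALSE]
    theta <- if (nrow(ok)) min(ok$theta) else NA_real_
    list(table = tab, theta = theta)
}

#' Rewrite subject segmentations with ensemble cluster labels
#'
#' Positive subject-level symbols are replaced by their ensemble cluster
#' ids; the transient label 0 is preserved. The result is the subjects x
#' time raster of cluster labels.
#'
#' @param seqs named list (by subject id) of relabeled
#'   \linkS4class{RecurrenceSegmentation} objects or integer vectors, all
#'   of the same length.
#' @param clustering an \linkS4class{EnsembleClustering} covering every
#'   (subject, positive symbol) pair occurring in \code{seqs}.
#' @return integer matrix, one row per subject, one column per time point.
#' @export
relabelEnsembleSequences <- function(seqs, clustering) {
    lab <- clusterLabels(clustering)
    subjects <- names(seqs)
    if (is.null(subjects))
        stop("relabelEnsembleSequences: 'seqs' must be named by subject")
    lens <- vapply(seqs, function(s)
        length(if (is(s, "RecurrenceSegmentation")) symbolSequence(s)
               else s), integer(1))
    if (length(unique(lens)) != 1L)
        stop("relabelEnsembleSequences: sequences differ in length")
    out <- matrix(0L, nrow = length(seqs), ncol = lens[1],
                  dimnames = list(subjects, NULL))
    for (r in seq_along(seqs)) {
        s <- seqs[[r]]
        s <- if (is(s, "RecurrenceSegmentation")) symbolSequence(s)
             else as.integer(s)
        pos <- unique(s[s > 0L])
        map <- integer(0)
        for (k in pos) {
            hit <- which(lab$subject == subjects[r] & lab$symbol == k)
            if (length(hit) != 1L)
                stop(sprintf(
                    "relabelEnsembleSequences: no cluster for (%s, %d)",
                    subjects[r], k))
            map[as.character(k)] <- lab$cluster[hit]
        }
        out[r, ] <- ifelse(s > 0L, map[as.character(s)], 0L)
    }
    out
}
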