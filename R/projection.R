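# Representative states and projection onto labeled region spaces.

#' Max-norm representative of a state cloud
#'
#' Returns the cloud member with the largest maximum (infinity) norm,
#' enhancing the contrast between metastable states compared with a
#' barycenter. Ties break toward the earliest time index.
#'
#' @param cloud a \linkS4class{StateCloud} (or a matrix of unit-norm rows,
#'   in which case row order stands in for time order).
#' @return list with elements \code{vector} (the representative state),
#'   \code{maxAbs} (its infinity norm), \code{timeIndex}, \code{subject}
#'   and \code{symbol}.
#' @export
representativeState <- function(cloud) {
    pts <- .cloudMatrix(cloud)
    if (nrow(pts) < 1L) stop("representativeState: empty state cloud")
    times <- if (is(cloud, "StateCloud")) cloudTimes(cloud)
             else seq_len(nrow(pts))
    infn <- apply(abs(pts), 1L, max)
    best <- which(infn == max(infn))
    best <- best[which.min(times[best])]
    list(vector = pts[best, ],
         maxAbs = infn[best],
         timeIndex = times[best],
         subject = if (is(cloud, "StateCloud")) cloud@subject
                   else NA_character_,
         symbol = if (is(cloud, "StateCloud")) cloud@symbol
                  else NA_integer_)
}

#' Project a state vector onto a region space
#'
#' Computes y = M x with M the K x M mixing matrix, mapping a module-space
#' state to a profile over K labeled regions (anatomical or functional).
#' Projection strengths may be negative, depending on the direction of the
#' basis vectors.
#'
#' @param x a representative state (as returned by
#'   [representativeState()]) or a numeric module-space vector.
#' @param mix a \linkS4class{MixingMatrix} whose column dimension equals
#'   the state dimension.
#' @return named numeric vector of K projection values.
#' @export
projectState <- function(x, mix) {
    v <- if (is.list(x)) x$vector else as.numeric(x)
    w <- mixingWeights(mix)
    if (ncol(w) != length(v))
        stop(sprintf(
            "projectState: state has %d modules but mixing matrix has %d columns",
            length(v), ncol(w)))
    y <- drop(w %*% v)
    names(y) <- regionLabels(mix)
    y
}

#' Rank regions by absolute projection strength
#'
#' @param profile named numeric projection profile (from
#'   [projectState()]).
#' @param top number of regions to return (at most \code{length(profile)}).
#' @return character vector of region labels sorted by descending absolute
#'   value; ties keep the label order of the profile.
#' @export
rankRegions <- function(profile, top = length(profile)) {
    if (top > length(profile))
        stop("rankRegions: 'top' exceeds the number of regions")
    ord <- order(-abs(profile), seq_along(profile))
    names(profile)[ord][seq_len(top)]
}

#' Read a mixing matrix from tab-separated text
#'
#' Expects region labels as row names (first column) and module ids as
#' column headers. When \code{nModules} is supplied and the table arrives
#' in the transposed (modules x regions) orientation, it is transposed
#' automatically with a message.
#'
#' @param file path to a TSV file.
#' @param nModules expected module dimension (optional, enables
#'   auto-transposition).
#' @param space region space tag ("AAL", "RSN" or "custom").
#' @return a \linkS4class{MixingMatrix}.
#' @export
readMixingMatrix <- function(file, nModules = NULL, space = "custom") {
    df <- read.delim(file, header = TRUE, row.names = 1L,
                     check.names = FALSE)
    w <- as.matrix(df)
    if (!is.null(nModules) && ncol(w) != nModules && nrow(w) == nModules) {
        message("readMixingMatrix: transposing to regions x modules")
        w <- t(w)
    }
    mixingMatrix(w, regionLabels = rownames(w), space = space)
}

#' @rdname readMixingMatrix
#' @param mix a \linkS4class{MixingMatrix} to write.
#' @export
writeMixingMatrix <- function(mix, file) {
    w <- mixingWeights(mix)
    if (is.null(colnames(w)))
        colnames(w) <- sprintf("module_%02d", seq_len(ncol(w)))
    df <- data.frame(region = regionLabels(mix), w, check.names = FALSE)
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Synthetic block-structured mixing matrix
#'
#' Emits a random nonnegative mixing matrix in which each region draws
#' positive weights from a contiguous block of modules -- a stand-in with
#' the shape of anatomical overlap matrices (45 labeled regions for the
#' AAL-like case) for exercising the projection stage.
#'
#' @param nModules module dimension M.
#' @param nRegions number of labeled regions K (default 45).
#' @param seed integer seed.
#' @param space region space tag.
#' @return a \linkS4class{MixingMatrix}.
#' @export
syntheticMixingMatrix <- function(nModules, nRegions = 45L, seed = 1L,
                                  space = "custom") {
    set.seed(seed)
    w <- matrix(0, nRegions, nModules)
    blockLen <- max(1L, ceiling(nModules / nRegions * 2))
    for (k in seq_len(nRegions)) {
        start <- sample.int(max(1L, nModules - blockLen + 1L), 1L)
        cols <- start:min(nModules, start + blockLen - 1L)
        w[k, cols] <- runif(length(cols))
    }
    labels <- sprintf("region_%02d", seq_len(nRegions))
    mixingMatrix(w, regionLabels = labels, space = space)
}
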