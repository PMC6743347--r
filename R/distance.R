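#' Cosine distance between unit vectors
#'
#' For unit-norm vectors x and y the cosine distance is
#' \code{1 - sum(x * y)}, bounded in [0, 2]: 0 for identical, 1 for
#' orthogonal and 2 for antipodal directions.
#'
#' @param x,y numeric vectors of equal length with unit Euclidean norm
#'   (checked to 1e-6).
#' @return a scalar in [0, 2].
#' @examples
#' cosineDistance(c(1, 0), c(0, 1))
#' @export
cosineDistance <- function(x, y) {
    if (length(x) != length(y))
        stop("cosineDistance: 'x' and 'y' must have the same length")
    .checkUnit(x, "x")
    .checkUnit(y, "y")
    1 - sum(x * y)
}

.checkUnit <- function(v, name) {
    if (abs(sqrt(sum(v^2)) - 1) > 1e-6)
        stop(sprintf("cosineDistance: '%s' is not unit-normalized", name))
    invisible(TRUE)
}

#' All pairwise cosine distances of a normalized trajectory
#'
#' @param x a normalized \linkS4class{StateTrajectory} or a matrix with
#'   unit-norm rows.
#' @return symmetric T x T matrix of cosine distances with zero diagonal.
#' @export
cosineDistanceMatrix <- function(x) {
    v <- trajValues(x)
    norms <- sqrt(rowSums(v^2))
    if (any(abs(norms - 1) > 1e-6))
        stop("cosineDistanceMatrix: rows must be unit-normalized")
    d <- 1 - tcrossprod(v)
    d <- (d + t(d)) / 2          # exact symmetry against rounding
    d[d < 0] <- 0
    diag(d) <- 0
    d
}
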