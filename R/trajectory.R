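#' Normalize a trajectory onto the unit hypersphere
#'
#' In mode \code{"unit"} each row (time point) is divided by its Euclidean
#' norm. In mode \code{"zscore_unit"} each column (module) is first
#' z-scored over time -- removing module amplitude offsets so that cosine
#' distance compares activation patterns -- and rows are then
#' unit-normalized. A zero-variance column under \code{"zscore_unit"} is
#' left centered only (with a warning); a row of zero norm is a degenerate
#' sample and raises an error naming the time index.
#'
#' @param x a \linkS4class{StateTrajectory} or numeric matrix.
#' @param mode \code{"zscore_unit"} (default) or \code{"unit"}.
#' @return a normalized \linkS4class{StateTrajectory}.
#' @examples
#' normalizeTrajectory(matrix(c(3, 4, 0, 5), 2, 2, byrow = TRUE), "unit")
#' @export
normalizeTrajectory <- function(x, mode = c("zscore_unit", "unit")) {
    mode <- match.arg(mode)
    si <- if (is(x, "StateTrajectory")) x@sampleInterval else numeric(0)
    v <- trajValues(x)
    if (mode == "zscore_unit") {
        mu <- colMeans(v)
        sdev <- apply(v, 2L, sd)
        zero_var <- sdev < 1e-12
        if (any(zero_var)) {
            warning(sprintf(
                "zero-variance column(s) %s left centered only",
                paste(which(zero_var), collapse = ", ")))
            sdev[zero_var] <- 1
        }
        v <- sweep(sweep(v, 2L, mu, "-"), 2L, sdev, "/")
    }
    norms <- sqrt(rowSums(v^2))
    bad <- which(norms < 1e-12)
    if (length(bad))
        stop(sprintf(
            "degenerate sample: zero-norm row at time index %s",
            paste(bad, collapse = ", ")))
    v <- v / norms
    stateTrajectory(v, sampleInterval = si, normalized = TRUE)
}

#' Read / write trajectories as tab-separated text
#'
#' The on-disk format is a TSV with a header row of module names and one
#' row per time point.
#'
#' @param file path to a TSV file.
#' @param sampleInterval optional sampling interval in seconds.
#' @return \code{readTrajectory} returns a \linkS4class{StateTrajectory}.
#' @export
readTrajectory <- function(file, sampleInterval = numeric(0)) {
    df <- tryCatch(
        read.delim(file, header = TRUE, check.names = FALSE),
        error = function(e) stop(sprintf(
            "failed to parse trajectory file '%s': %s", file,
            conditionMessage(e))))
    m <- as.matrix(df)
    if (!is.numeric(m)) {
        bad <- which(!vapply(df, is.numeric, logical(1)))
        stop(sprintf(
            "trajectory file '%s': non-numeric column(s) %s", file,
            paste(names(df)[bad], collapse = ", ")))
    }
    stateTrajectory(m, sampleInterval = sampleInterval)
}

#' @rdname readTrajectory
#' @param x a \linkS4class{StateTrajectory} or matrix to write.
#' @export
writeTrajectory <- function(x, file) {
    v <- trajValues(x)
    if (is.null(colnames(v)))
        colnames(v) <- sprintf("module_%02d", seq_len(ncol(v)))
    write.table(v, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Embed a low-dimensional trajectory into a higher-dimensional space
#'
#' Applies a seeded random column-orthonormal linear map (preserving all
#' pairwise inner products) plus optional isotropic Gaussian noise. Lets
#' the low-dimensional switching simulators exercise the full M-module
#' pipeline.
#'
#' @param x a \linkS4class{StateTrajectory} or matrix (T x m).
#' @param MTarget target dimension, at least the input dimension.
#' @param seed integer seed for the random map (and noise).
#' @param noiseSigma standard deviation of added isotropic noise.
#' @return a \linkS4class{StateTrajectory} with \code{MTarget} columns.
#' @export
embedTrajectory <- function(x, MTarget, seed = 1L, noiseSigma = 0) {
    v <- trajValues(x)
    m <- ncol(v)
    if (MTarget < m)
        stop("embedTrajectory: 'MTarget' must be >= the input dimension")
    si <- if (is(x, "StateTrajectory")) x@sampleInterval else numeric(0)
    set.seed(seed)
    basis <- qr.Q(qr(matrix(rnorm(MTarget * m), MTarget, m)))  # MTarget x m
    out <- v %*% t(basis)
    if (noiseSigma > 0)
        out <- out + matrix(rnorm(length(out), sd = noiseSigma),
                            nrow(out), ncol(out))
    stateTrajectory(out, sampleInterval = si)
}
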