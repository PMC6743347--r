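# Plain-text report writers: everything the pipeline emits is TSV or
# structured text so results diff cleanly.

#' Write a segmentation as two-column TSV
#'
#' Columns: time_index, symbol (0 = transient).
#'
#' @param seg a \linkS4class{RecurrenceSegmentation}.
#' @param file output path.
#' @export
writeSegmentation <- function(seg, file) {
    s <- symbolSequence(seg)
    write.table(data.frame(time_index = seq_along(s), symbol = s),
                file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Write a utility curve as TSV plus a summary record
#'
#' The grid goes into a three-column TSV (epsilon, utility, complexity);
#' a structured-text summary (best epsilon, n, dwell counts) is appended
#' as comment lines prefixed with '#'.
#'
#' @param curve a \linkS4class{UtilityCurve}.
#' @param file output path.
#' @export
writeUtilityCurve <- function(curve, file) {
    seg <- bestSegmentation(curve)
    s <- symbolSequence(seg)
    dwell <- table(s[s > 0L])
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(sprintf("# best_epsilon\t%.10g", bestEpsilon(curve)), con)
    writeLines(sprintf("# n_states\t%d", nStates(seg)), con)
    if (length(dwell))
        writeLines(sprintf("# dwell\t%s\t%d", names(dwell),
                           as.integer(dwell)), con)
    write.table(utilityTable(curve), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(file)
}

#' Write a Hausdorff distance matrix as square TSV
#'
#' Row/column headers are the pooled "subject:symbol" identifiers.
#'
#' @param D a \linkS4class{HausdorffMatrix}.
#' @param file output path.
#' @export
writeHausdorffMatrix <- function(D, file) {
    idx <- hausdorffIndex(D)
    ids <- sprintf("%s:%d", idx$subject, idx$symbol)
    m <- hausdorffValues(D)
    dimnames(m) <- list(ids, ids)
    write.table(m, file, sep = "\t", quote = FALSE, col.names = NA)
    invisible(file)
}

#' Write an ensemble clustering as structured text
#'
#' @param clustering an \linkS4class{EnsembleClustering}.
#' @param file output path.
#' @export
writeClustering <- function(clustering, file) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(sprintf("# theta\t%.10g", clustering@theta), con)
    writeLines(sprintf("# n_clusters\t%d", nClusters(clustering)), con)
    write.table(clusterLabels(clustering), con, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Write a subjects-by-time cluster raster as TSV
#'
#' @param raster integer matrix from [relabelEnsembleSequences()].
#' @param file output path.
#' @export
writeRaster <- function(raster, file) {
    df <- data.frame(subject = rownames(raster), raster,
                     check.names = FALSE)
    colnames(df) <- c("subject", sprintf("t%d", seq_len(ncol(raster))))
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Write a projection profile as two-column TSV
#'
#' Columns: region, value.
#'
#' @param profile named numeric vector from [projectState()].
#' @param file output path.
#' @export
writeProjectionProfile <- function(profile, file) {
    write.table(data.frame(region = names(profile),
                           value = unname(profile)),
                file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}
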