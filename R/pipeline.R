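# Orchestration: per-subject segmentation, module-count complexity sweep
# and ensemble clustering with projection.

#' Pipeline configuration
#'
#' Collects every free analysis parameter in one validated object so runs
#' are reproducible: normalization mode, ball-size grid specification,
#' minimal dwell, Hausdorff threshold (scalar or search grid) and seed.
#'
#' @param normalization "zscore_unit" (default) or "unit"; passed to
#'   [normalizeTrajectory()].
#' @param grid ball-size grid: NULL for the automatic linear percentile
#'   grid, the string "log" for the logarithmic percentile grid of
#'   [epsilonGrid()] (recommended for densely sampled deterministic
#'   flows), or an explicit increasing numeric vector.
#' @param minDwell minimal class size that counts as metastable.
#' @param theta Hausdorff threshold; a scalar uses that value, a numeric
#'   vector triggers [selectTheta()] over the grid.
#' @param seed integer seed recorded with every report.
#' @return a configuration list of class "PipelineConfig".
#' @export
pipelineConfig <- function(normalization = c("zscore_unit", "unit"),
                           grid = NULL, minDwell = 2L, theta = 0.8,
                           seed = 1L) {
    normalization <- match.arg(normalization)
    if (!is.null(grid) && !identical(grid, "log") && !is.numeric(grid))
        stop("pipelineConfig: 'grid' must be NULL, \"log\" or numeric")
    if (any(theta <= 0))
        stop("pipelineConfig: 'theta' must be positive")
    structure(list(normalization = normalization, grid = grid,
                   minDwell = as.integer(minDwell), theta = theta,
                   seed = as.integer(seed)),
              class = "PipelineConfig")
}

.resolveGrid <- function(traj, grid) {
    if (is.null(grid)) return(NULL)                 # optimizeEpsilon default
    if (identical(grid, "log")) return(epsilonGrid(traj, scale = "log"))
    grid
}

#' Run the subject-level segmentation pipeline
#'
#' Normalization, ball-size optimization and transient relabeling in one
#' deterministic step: the trajectory is normalized, the Markov utility is
#' maximized over the ball-size grid, and the segmentation at the optimal
#' ball size is returned together with its state clouds and a summary
#' report (complexity, optimal epsilon, dwell statistics).
#'
#' @param x a trajectory: file path (TSV), numeric matrix or
#'   \linkS4class{StateTrajectory}.
#' @param cfg a [pipelineConfig()].
#' @param subject subject identifier for the extracted state clouds.
#' @return list with elements \code{segmentation}
#'   (\linkS4class{RecurrenceSegmentation} at the optimal ball size),
#'   \code{utilityCurve} (\linkS4class{UtilityCurve}), \code{partition}
#'   (\linkS4class{MetastablePartition}) and \code{report} (named list:
#'   complexity, bestEpsilon, nStates, dwellCounts, transientFraction,
#'   config echo).
#' @export
runSubjectPipeline <- function(x, cfg = pipelineConfig(),
                               subject = "subject1") {
    stopifnot(inherits(cfg, "PipelineConfig"))
    traj <- if (is.character(x)) readTrajectory(x) else x
    norm <- normalizeTrajectory(traj, mode = cfg$normalization)
    curve <- optimizeEpsilon(norm, grid = .resolveGrid(norm, cfg$grid),
                             minDwell = cfg$minDwell)
    seg <- bestSegmentation(curve)
    partition <- extractStates(norm, seg, subject = subject)
    s <- symbolSequence(seg)
    dwellCounts <- table(s[s > 0L])
    report <- list(subject = subject,
                   complexity = segmentationComplexity(seg),
                   bestEpsilon = bestEpsilon(curve),
                   nStates = nStates(seg),
                   dwellCounts = dwellCounts,
                   transientFraction = mean(s == 0L),
                   config = unclass(cfg))
    list(segmentation = seg, utilityCurve = curve, partition = partition,
         report = report)
}

#' Segmentation complexity across module counts
#'
#' Runs the subject pipeline for every module count of an ensemble and
#' summarizes the per-subject complexities (number of metastable states)
#' as mean and standard deviation per count. With a single subject the
#' standard deviation is reported as 0 by convention.
#'
#' @param ensembles either a named list -- one entry per module count,
#'   each a list of per-subject trajectories -- with names parseable as
#'   integers, or a directory containing one subdirectory \code{M<count>}
#'   per module count with one trajectory TSV per subject.
#' @param moduleCounts integer module counts to evaluate (defaults to all
#'   entries of \code{ensembles}).
#' @param cfg a [pipelineConfig()].
#' @return data.frame with columns moduleCount, meanComplexity,
#'   sdComplexity and nSubjects; the per-subject complexity matrix is
#'   attached as \code{attr(, "perSubject")}.
#' @export
complexitySweep <- function(ensembles, moduleCounts = NULL,
                            cfg = pipelineConfig()) {
    fromDir <- is.character(ensembles)
    if (is.null(moduleCounts)) {
        if (fromDir)
            stop("complexitySweep: 'moduleCounts' is required with a directory")
        moduleCounts <- as.integer(names(ensembles))
    }
    perSubject <- list()
    for (m in moduleCounts) {
        if (fromDir) {
            dir <- file.path(ensembles, sprintf("M%d", m))
            files <- sort(list.files(dir, pattern = "\\.tsv$",
                                     full.names = TRUE))
            if (!length(files))
                stop(sprintf(
                    "complexitySweep: no trajectories for module count %d (missing %s)",
                    m, dir))
            trajs <- files
        } else {
            trajs <- ensembles[[as.character(m)]]
            if (is.null(trajs))
                stop(sprintf(
                    "complexitySweep: no ensemble entry for module count %d", m))
        }
        perSubject[[as.character(m)]] <- vapply(
            seq_along(trajs),
            function(i) runSubjectPipeline(
                trajs[[i]], cfg,
                subject = sprintf("subject%02d", i))$report$complexity,
            numeric(1))
    }
    res <- data.frame(
        moduleCount = moduleCounts,
        meanComplexity = vapply(perSubject, mean, numeric(1)),
        sdComplexity = vapply(perSubject, function(v)
            if (length(v) > 1L) sd(v) else 0, numeric(1)),
        nSubjects = vapply(perSubject, length, integer(1)),
        row.names = NULL)
    attr(res, "perSubject") <- perSubject
    res
}

#' Run the ensemble-level clustering pipeline
#'
#' Pools the metastable state clouds of all subjects, computes pairwise
#' Hausdorff distances, clusters them at the configured threshold (or
#' over a threshold grid via [selectTheta()]), rewrites the subject
#' segmentations with cluster labels and, when a mixing matrix is
#' supplied, projects each cluster's max-norm representative onto the
#' region space.
#'
#' @param subjectResults named list (by subject) of [runSubjectPipeline()]
#'   results; needs at least 2 subjects with nonempty metastable sets.
#' @param cfg a [pipelineConfig()] (its \code{theta} is used).
#' @param mixing optional \linkS4class{MixingMatrix}.
#' @return list with \code{clustering}
#'   (\linkS4class{EnsembleClustering}), \code{distances}
#'   (\linkS4class{HausdorffMatrix}), \code{raster} (subjects x time
#'   cluster-label matrix), \code{coverage} (from [coverageReport()]),
#'   \code{thetaTable} (threshold search table or NULL) and
#'   \code{profiles} (per-cluster projection profiles or NULL).
#' @export
runEnsemblePipeline <- function(subjectResults, cfg = pipelineConfig(),
                                mixing = NULL) {
    stopifnot(inherits(cfg, "PipelineConfig"))
    if (length(subjectResults) < 2L)
        stop("runEnsemblePipeline: need at least 2 subjects")
    if (is.null(names(subjectResults)))
        names(subjectResults) <-
            sprintf("subject%02d", seq_along(subjectResults))
    clouds <- list()
    for (sb in names(subjectResults)) {
        part <- subjectResults[[sb]]$partition
        for (cl in part@clouds) {
            cl@subject <- sb
            clouds[[length(clouds) + 1L]] <- cl
        }
    }
    if (!length(clouds))
        stop("runEnsemblePipeline: empty ensemble (no metastable states)")
    D <- hausdorffMatrix(clouds)
    thetaTable <- NULL
    theta <- cfg$theta
    if (length(theta) > 1L) {
        sel <- selectTheta(D, theta)
        thetaTable <- sel$table
        if (is.na(sel$theta))
            stop("runEnsemblePipeline: no threshold achieves full coverage")
        theta <- sel$theta
    }
    clustering <- clusterStates(D, theta)
    seqs <- lapply(subjectResults, `[[`, "segmentation")
    raster <- relabelEnsembleSequences(seqs, clustering)
    coverage <- coverageReport(clustering,
                               subjects = names(subjectResults))
    profiles <- NULL
    if (!is.null(mixing)) {
        lab <- clusterLabels(clustering)
        profiles <- lapply(sort(unique(lab$cluster)), function(k) {
            members <- which(lab$cluster == k)
            pts <- do.call(rbind, lapply(members, function(i)
                cloudPoints(clouds[[i]])))
            rep <- representativeState(pts)
            profile <- projectState(rep, mixing)
            list(cluster = k, representative = rep, profile = profile)
        })
        names(profiles) <- sprintf("cluster%d",
                                   sort(unique(lab$cluster)))
    }
    list(clustering = clustering, distances = D, raster = raster,
         coverage = coverage, thetaTable = thetaTable,
         profiles = profiles)
}
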