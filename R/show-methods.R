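# Compact show() methods for the pipeline containers.

setMethod("show", "StateTrajectory", function(object) {
    cat(sprintf("StateTrajectory: %d time points x %d modules%s\n",
                nTimes(object), nModules(object),
                if (isNormalized(object)) " (unit-normalized)" else ""))
    if (length(object@sampleInterval))
        cat(sprintf("  sample interval: %.4g s\n", object@sampleInterval))
})

setMethod("show", "RecurrencePlot", function(object) {
    m <- rpMatrix(object)
    offd <- sum(m) - nrow(m)
    cat(sprintf(
        "RecurrencePlot: T = %d, epsilon = %.4g, recurrence rate %.3f\n",
        nrow(m), rpEpsilon(object), offd / (nrow(m)^2 - nrow(m))))
})

setMethod("show", "RecurrenceSegmentation", function(object) {
    s <- symbolSequence(object)
    cat(sprintf(
        "RecurrenceSegmentation: T = %d, %d metastable state(s)%s\n",
        length(s), segmentationComplexity(object),
        if (object@relabeled)
            sprintf(", %.1f%% transient", 100 * mean(s == 0L))
        else " (not yet relabeled)"))
})

setMethod("show", "MetastablePartition", function(object) {
    cat(sprintf(
        "MetastablePartition: %d cloud(s), %d transient of %d time points\n",
        length(object@clouds), length(object@transientTimes),
        object@nTime))
})

setMethod("show", "StateCloud", function(object) {
    cat(sprintf("StateCloud: subject %s, symbol %d, %d point(s) in %d-D\n",
                object@subject, object@symbol, nrow(object@points),
                ncol(object@points)))
})

setMethod("show", "TransitionModel", function(object) {
    cat(sprintf("TransitionModel: %d state(s)%s, trace %.3f\n",
                nrow(object@probs),
                if (0L %in% object@states) " (incl. transient)" else "",
                sum(diag(object@probs))))
})

setMethod("show", "UtilityCurve", function(object) {
    cat(sprintf(
        "UtilityCurve: %d ball sizes in [%.4g, %.4g]; best epsilon %.4g (u = %.4f, complexity %d)\n",
        length(object@epsilons), min(object@epsilons),
        max(object@epsilons), object@bestEpsilon,
        max(object@utilities),
        object@complexities[which.max(object@utilities)]))
})

setMethod("show", "HausdorffMatrix", function(object) {
    cat(sprintf("HausdorffMatrix: %d pooled cloud(s) from %d subject(s)\n",
                nrow(object@dist),
                length(unique(object@index$subject))))
})

setMethod("show", "EnsembleClustering", function(object) {
    cat(sprintf(
        "EnsembleClustering: %d cluster(s) over %d cloud(s) at theta = %.4g\n",
        object@nClusters, nrow(object@labels), object@theta))
})

setMethod("show", "MixingMatrix", function(object) {
    cat(sprintf("MixingMatrix (%s): %d regions x %d modules\n",
                object@space, nrow(object@weights),
                ncol(object@weights)))
})
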