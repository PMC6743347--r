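# Recurrence plots, the recurrence grammar and transient relabeling.

test_that("cosine distance matches its closed form on unit vectors", {
    expect_equal(cosineDistance(c(1, 0), c(1, 0)), 0)
    expect_equal(cosineDistance(c(1, 0), c(0, 1)), 1)
    expect_equal(cosineDistance(c(1, 0), c(-1, 0)), 2)
    expect_error(cosineDistance(c(1, 0), c(1, 0, 0)), "length")
    expect_error(cosineDistance(c(2, 0), c(1, 0)), "unit")
    # symmetry and range on random unit vectors
    set.seed(1)
    for (k in 1:20) {
        x <- rnorm(5); x <- x / sqrt(sum(x^2))
        y <- rnorm(5); y <- y / sqrt(sum(y^2))
        d <- cosineDistance(x, y)
        expect_equal(d, cosineDistance(y, x))
        expect_true(d >= 0 && d <= 2)
    }
})

test_that("trajectory normalization modes behave as specified", {
    # 3-4-5 triangle under plain unit normalization
    out <- trajValues(normalizeTrajectory(rbind(c(3, 4), c(0, 5)), "unit"))
    expect_equal(out[1, ], c(0.6, 0.8))
    # idempotence on already-normalized rows
    again <- trajValues(normalizeTrajectory(out, "unit"))
    expect_equal(again, out)
    # hand-computed z-score + unit norm of a 2x2 matrix
    z <- trajValues(normalizeTrajectory(rbind(c(1, 2), c(3, 4)),
                                        "zscore_unit"))
    expect_equal(z, rbind(c(-1, -1) / sqrt(2), c(1, 1) / sqrt(2)))
    # degenerate zero row names the time index
    expect_error(normalizeTrajectory(rbind(c(1, 1), c(0, 0)), "unit"),
                 "time index 2")
    # zero-variance column is left centered only, with a warning
    expect_warning(
        res <- normalizeTrajectory(cbind(c(1, 1, 1), c(1, 2, 4)),
                                   "zscore_unit"),
        "zero-variance")
    expect_true(isNormalized(res))
})

test_that("recurrence plot implements the strict epsilon ball", {
    e1 <- c(1, 0); e2 <- c(0, 1)
    traj <- stateTrajectory(rbind(e1, e2, e1), normalized = TRUE)
    rp <- recurrencePlot(traj, 0.5)
    m <- rpMatrix(rp)
    expect_true(all(diag(m)))
    off <- which(m & upper.tri(m), arr.ind = TRUE)
    expect_equal(unname(as.vector(off)), c(1L, 3L))  # only pair (1, 3)
    # epsilon above the cosine-distance bound gives the all-ones plot
    expect_true(all(rpMatrix(recurrencePlot(traj, 2.1))))
    # epsilon below the minimal nonzero distance gives the identity
    distinct <- stateTrajectory(diag(3), normalized = TRUE)
    expect_equal(rpMatrix(recurrencePlot(distinct, 0.5)),
                 diag(3) == 1, ignore_attr = TRUE)
    expect_error(recurrencePlot(traj, 0), "positive")
    expect_error(recurrencePlot(traj, -1), "positive")
})

test_that("recurrence plots are symmetric with unit diagonal", {
    set.seed(42)
    for (k in 1:10) {
        traj <- stateTrajectory(randomUnitCloud(30, 4), normalized = TRUE)
        rp <- rpMatrix(recurrencePlot(traj, runif(1, 0.05, 1.5)))
        expect_identical(rp, t(rp))
        expect_true(all(diag(rp)))
    }
})

test_that("grammar fixed point labels components by minimal time index", {
    mkRP <- function(m) new("RecurrencePlot", matrix = m, epsilon = 0.1)
    # identity plot: no rules
    id <- diag(4) == 1
    expect_equal(symbolSequence(recurrenceSegment(mkRP(id))), 1:4)
    # all-ones plot: single component
    expect_equal(symbolSequence(recurrenceSegment(
        mkRP(matrix(TRUE, 4, 4)))), rep(1L, 4))
    # recurrent pairs (3,1) and (5,3): components {1,3,5}, {2}, {4}
    m <- diag(5) == 1
    m[3, 1] <- m[1, 3] <- TRUE
    m[5, 3] <- m[3, 5] <- TRUE
    expect_equal(symbolSequence(recurrenceSegment(mkRP(m))),
                 c(1L, 2L, 1L, 4L, 1L))
})

test_that("grammar fixed point equals the connected-component oracle", {
    skip_if_not_installed("igraph")
    set.seed(99)
    for (k in 1:30) {
        nT <- sample(5:120, 1)
        m <- randomRecurrenceMatrix(nT)
        rp <- new("RecurrencePlot", matrix = m, epsilon = 0.1)
        expect_identical(symbolSequence(recurrenceSegment(rp)),
                         componentMinOracle(m))
    }
})

test_that("the grammar is idempotent at its fixed point", {
    set.seed(7)
    for (k in 1:10) {
        m <- randomRecurrenceMatrix(sample(10:80, 1))
        rp <- new("RecurrencePlot", matrix = m, epsilon = 0.1)
        fp <- symbolSequence(recurrenceSegment(rp))
        expect_identical(applyRecurrenceGrammar(fp, rp, passes = 1L), fp)
        expect_identical(applyRecurrenceGrammar(fp, rp, passes = -1L), fp)
    }
})

test_that("extreme ball sizes give the one-class and all-transient limits", {
    set.seed(3)
    traj <- stateTrajectory(randomUnitCloud(40, 6), normalized = TRUE)
    big <- relabelTransients(recurrenceSegment(recurrencePlot(traj, 2.5)))
    expect_equal(segmentationComplexity(big), 1L)
    d <- cosineDistanceMatrix(traj)
    tiny <- relabelTransients(recurrenceSegment(
        recurrencePlot(traj, min(d[upper.tri(d)]) / 2)))
    expect_equal(segmentationComplexity(tiny), 0L)
    expect_true(all(symbolSequence(tiny) == 0L))
})

test_that("transient relabeling keeps only classes above the dwell cutoff", {
    seg <- new("RecurrenceSegmentation",
               symbols = c(1L, 2L, 1L, 4L, 1L), relabeled = FALSE)
    rel <- relabelTransients(seg)
    expect_equal(symbolSequence(rel), c(1L, 0L, 1L, 0L, 1L))
    expect_equal(nStates(rel), 2L)
    allSame <- relabelTransients(new("RecurrenceSegmentation",
                                     symbols = rep(1L, 3), relabeled = FALSE))
    expect_equal(symbolSequence(allSame), rep(1L, 3))
    expect_equal(nStates(allSame), 2L)
    allSingle <- relabelTransients(new("RecurrenceSegmentation",
                                       symbols = 1:3, relabeled = FALSE))
    expect_equal(symbolSequence(allSingle), rep(0L, 3))
    expect_equal(nStates(allSingle), 1L)
    expect_error(relabelTransients(seg, minDwell = 0), "positive")
})

test_that("extracted state clouds partition the time axis", {
    traj <- stateTrajectory(randomUnitCloud(3, 4), normalized = TRUE)
    seg <- new("RecurrenceSegmentation", symbols = c(1L, 0L, 1L),
               relabeled = TRUE, minDwell = 2L)
    part <- extractStates(traj, seg)
    expect_length(part@clouds, 1L)
    expect_equal(cloudTimes(part@clouds[[1]]), c(1L, 3L))
    expect_equal(part@transientTimes, 2L)
    # all transient
    seg0 <- new("RecurrenceSegmentation", symbols = c(0L, 0L, 0L),
                relabeled = TRUE, minDwell = 2L)
    part0 <- extractStates(traj, seg0)
    expect_length(part0@clouds, 0L)
    expect_equal(part0@transientTimes, 1:3)
    # two classes of size two, partition property on a random case
    traj4 <- stateTrajectory(randomUnitCloud(4, 4), normalized = TRUE)
    part4 <- extractStates(traj4, new("RecurrenceSegmentation",
                                      symbols = c(1L, 1L, 4L, 4L),
                                      relabeled = TRUE, minDwell = 2L))
    idx <- sort(unlist(lapply(part4@clouds, cloudTimes)))
    expect_equal(idx, 1:4)
    expect_error(extractStates(traj, new("RecurrenceSegmentation",
                                         symbols = c(1L, 1L),
                                         relabeled = TRUE, minDwell = 2L)),
                 "length")
})
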