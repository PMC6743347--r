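# Transition-matrix estimation, the Markov utility and ball-size choice.

test_that("transition matrices follow the bigram-counting contract", {
    tm <- estimateTransitionMatrix(c(1L, 0L, 1L, 0L, 1L))
    expect_equal(modelStates(tm), c(0L, 1L))
    expect_equal(transitionProbs(tm), rbind(c(0, 1), c(1, 0)),
                 ignore_attr = TRUE)
    # single self-transitioning state
    tm1 <- estimateTransitionMatrix(c(1L, 1L, 1L, 1L))
    expect_equal(transitionProbs(tm1), matrix(1, 1, 1), ignore_attr = TRUE)
    expect_equal(modelStates(tm1), 1L)
    # final-state column is absorbing
    tm2 <- estimateTransitionMatrix(c(1L, 1L, 0L))
    i0 <- match(0L, modelStates(tm2)); i1 <- match(1L, modelStates(tm2))
    expect_equal(transitionProbs(tm2)[i0, i1], 0.5)
    expect_equal(transitionProbs(tm2)[i1, i1], 0.5)
    expect_equal(transitionProbs(tm2)[i0, i0], 1)   # absorbing column
    expect_error(estimateTransitionMatrix(integer(0)), "2 time points")
    expect_error(estimateTransitionMatrix(1L), "2 time points")
})

test_that("estimated transition matrices are column stochastic", {
    set.seed(5)
    for (k in 1:40) {
        s <- sample(0:4, sample(2:60, 1), replace = TRUE)
        P <- transitionProbs(estimateTransitionMatrix(as.integer(s)))
        expect_true(all(abs(colSums(P) - 1) < 1e-12))
        expect_true(all(P >= 0 & P <= 1))
    }
})

test_that("the Markov utility reproduces its closed forms", {
    id3 <- new("TransitionModel", probs = diag(3), states = c(0L, 1L, 2L))
    expect_equal(markovUtility(id3), 0.6)
    worked <- new("TransitionModel",
                  probs = cbind(c(0, 0.5, 0.5), c(0.2, 0.8, 0),
                                c(0.2, 0, 0.8)),
                  states = c(0L, 1L, 2L))
    expect_equal(markovUtility(worked), 0.72)
    # alternating transient/metastable chain: (0 + 1 + 1) / 4
    expect_equal(markovUtility(estimateTransitionMatrix(
        c(1L, 0L, 1L, 0L, 1L))), 0.5)
    # all-transient sequence scores p00 / 3
    expect_equal(markovUtility(estimateTransitionMatrix(
        c(0L, 0L, 0L))), 1 / 3)
    bad <- new("TransitionModel", probs = diag(2), states = c(0L, 1L))
    bad@probs[1, 1] <- 0.5   # break stochasticity after validity
    expect_error(markovUtility(bad), "sum to 1")
})

test_that("the utility is bounded in [0, 1] on random stochastic models", {
    set.seed(11)
    for (k in 1:200) {
        tm <- randomTransitionModel(sample(1:12, 1))
        u <- markovUtility(tm)
        expect_true(u >= 0 && u <= 1)
    }
})

test_that("segmentation complexity counts positive classes", {
    expect_equal(segmentationComplexity(c(1L, 0L, 1L, 0L, 1L)), 1L)
    expect_equal(segmentationComplexity(c(0L, 0L, 0L)), 0L)
    expect_equal(segmentationComplexity(c(1L, 1L, 5L, 5L, 1L)), 2L)
})

test_that("ball-size optimization recovers two antipodal clusters", {
    traj <- twoClusterTrajectory()
    curve <- optimizeEpsilon(traj)
    expect_equal(segmentationComplexity(bestSegmentation(curve)), 2L)
    expect_true(all(curve@utilities >= 0 & curve@utilities <= 1))
    expect_equal(bestEpsilon(curve),
                 curve@epsilons[which.max(curve@utilities)])
})

test_that("degenerate grids and inputs follow the tie-break conventions", {
    # all rows identical: every epsilon yields one state; the first grid
    # value wins the tie
    traj <- stateTrajectory(matrix(rep(c(1, 0), each = 10), 10, 2),
                            normalized = TRUE)
    curve <- optimizeEpsilon(traj)
    expect_equal(bestEpsilon(curve), curve@epsilons[1])
    expect_true(all(curve@complexities == 1L))
    expect_error(optimizeEpsilon(traj, grid = numeric(0)), "empty")
    expect_error(optimizeEpsilon(traj, grid = c(0.5, 0.2)), "increasing")
    expect_error(optimizeEpsilon(traj, grid = c(-1, 0.5)),
                 "increasing and positive")
})

test_that("epsilon grids are increasing, positive and scale-aware", {
    set.seed(2)
    traj <- stateTrajectory(randomUnitCloud(50, 5), normalized = TRUE)
    for (scale in c("linear", "log")) {
        g <- epsilonGrid(traj, scale = scale)
        expect_true(all(g > 0))
        expect_false(is.unsorted(g, strictly = TRUE))
    }
    # log grid resolves the small-distance end more finely
    glin <- epsilonGrid(traj, scale = "linear")
    glog <- epsilonGrid(traj, scale = "log")
    expect_lt(glog[1], glin[1] + 1e-12)
})
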