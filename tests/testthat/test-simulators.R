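# The three canonical switching simulators: structural contracts and
# integrator behavior. Recovery of the two-state structure by the full
# analysis lives in the acceptance suite.

test_that("the slow-fast system alternates between its two branches", {
    traj <- simulateSlowFast()
    v <- trajValues(traj)
    branch <- ifelse(v[, 2] > 0.5, 1L, ifelse(v[, 2] < -0.5, -1L, 0L))
    runs <- rle(branch[branch != 0L])$values
    expect_gte(length(runs) - 1L, 6L)       # at least 6 transitions
    expect_setequal(unique(runs), c(-1L, 1L))
    # x2 stays near the two activity levels most of the time
    expect_gt(mean(abs(abs(v[, 2]) - 1) < 0.25), 0.9)
})

test_that("freezing the slow variable keeps one activity branch", {
    cfg <- slowFastConfig(epsTimescale = 1e-9, tEnd = 100, dt = 0.05,
                          sampleEvery = 10L)
    v <- trajValues(simulateSlowFast(cfg))
    expect_true(all(abs(v[, 2] - 1) < 0.1))   # never leaves the branch
    expect_lt(diff(range(v[, 1])), 1e-6)      # slow variable frozen
})

test_that("the deterministic integrators converge at fourth order", {
    endpoint <- function(cfg) {
        v <- trajValues(simulateSlowFast(cfg))
        v[nrow(v), ]
    }
    mk <- function(dt) slowFastConfig(initialState = c(0, 0.5),
                                      tEnd = 4, dt = dt, sampleEvery = 1L)
    ref <- endpoint(mk(0.0025))
    errCoarse <- max(abs(endpoint(mk(0.02)) - ref))
    errFine <- max(abs(endpoint(mk(0.01)) - ref))
    expect_gt(errCoarse / errFine, 8)    # ~16 for a 4th-order method
    expect_lt(errCoarse / errFine, 40)
    endpointR <- function(dt) {
        cfg <- riddledConfig(tEnd = 4, dt = dt, sampleEvery = 1L)
        v <- trajValues(simulateRiddled(cfg))
        v[nrow(v), ]
    }
    refR <- endpointR(0.0025)
    ratioR <- max(abs(endpointR(0.02) - refR)) /
        max(abs(endpointR(0.01) - refR))
    expect_gt(ratioR, 8)
    expect_lt(ratioR, 40)
})

test_that("unforced bistable oscillators stay in one well", {
    cfg <- riddledConfig(A = 0, tEnd = 1500, sampleEvery = 100L)
    v <- trajValues(simulateRiddled(cfg))
    expect_true(all(v[, 1] > 0))          # never leaves the initial well
    norm <- normalizeTrajectory(v, "unit")
    curve <- optimizeEpsilon(norm, grid = epsilonGrid(norm, scale = "log"),
                             minDwell = 5L)
    expect_equal(segmentationComplexity(bestSegmentation(curve)), 1L)
})

test_that("the forced system visits both wells for long dwell episodes", {
    v <- trajValues(simulateRiddled())
    w <- sign(v[, 1])
    runs <- rle(w[w != 0])
    expect_gte(length(runs$lengths) - 1L, 6L)
    expect_setequal(unique(runs$values), c(-1, 1))
    expect_gt(mean(runs$lengths), 10)     # dwells are long in samples
})

test_that("the heteroclinic poles are exact equilibria", {
    cfg <- heteroclinicConfig()
    expect_equal(heteroclinicDrift(c(0, 0, 0, 1), cfg), rep(0, 4))
    expect_equal(heteroclinicDrift(c(0, 0, 0, -1), cfg), rep(0, 4))
    # a generic sphere point is not an equilibrium
    x <- c(0.5, 0.5, 0.5, 0.5)
    expect_gt(max(abs(heteroclinicDrift(x, cfg))), 1e-3)
    # the drift is tangent to the sphere everywhere
    set.seed(15)
    for (k in 1:10) {
        x <- rnorm(4); x <- x / sqrt(sum(x^2))
        expect_lt(abs(sum(x * heteroclinicDrift(x, cfg))), 1e-12)
    }
})

test_that("noise-free runs conserve the sphere and slow down monotonically", {
    cfg <- heteroclinicConfig(noiseA = 0, tEnd = 150)
    traj <- simulateHeteroclinic(cfg)
    v <- trajValues(traj)
    expect_lt(max(abs(sqrt(rowSums(v^2)) - 1)), 1e-8)
    pas <- heteroclinicPassages(traj)
    expect_gte(nrow(pas), 4L)
    # successive passages near the saddles take ever longer (skip the
    # initial-condition episode)
    expect_false(is.unsorted(pas$duration[-1]))
    expect_setequal(unique(pas$pole), c(-1, 1))
})

test_that("noisy heteroclinic runs switch recurrently and reproducibly", {
    traj <- simulateHeteroclinic(heteroclinicConfig(seed = 5))
    pas <- heteroclinicPassages(traj)
    expect_gte(sum(pas$pole == 1), 3L)
    expect_gte(sum(pas$pole == -1), 3L)
    again <- simulateHeteroclinic(heteroclinicConfig(seed = 5))
    expect_identical(trajValues(traj), trajValues(again))
    other <- simulateHeteroclinic(heteroclinicConfig(seed = 6))
    expect_false(identical(trajValues(traj), trajValues(other)))
})
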