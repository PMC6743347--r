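# Hausdorff distances between state clouds and ensemble clustering.

test_that("Hausdorff distance matches hand-derived cases", {
    e1 <- rbind(c(1, 0)); e2 <- rbind(c(0, 1))
    both <- rbind(c(1, 0), c(0, 1))
    expect_equal(hausdorffDistance(both, both), 0)
    expect_equal(hausdorffDistance(e1, e2), 1)
    # directed distance from the uncovered point dominates
    expect_equal(hausdorffDistance(both, e1), 1)
    expect_equal(hausdorffDistance(e1, both), 1)   # symmetry
    expect_error(hausdorffDistance(e1, matrix(0, 0, 2)), "empty")
    expect_error(hausdorffDistance(e1, rbind(c(1, 0, 0))), "dimension")
})

test_that("Hausdorff distance equals the brute-force oracle", {
    set.seed(21)
    for (k in 1:30) {
        m <- sample(2:6, 1)
        A <- randomUnitCloud(sample(1:15, 1), m)
        B <- randomUnitCloud(sample(1:15, 1), m)
        expect_equal(hausdorffDistance(A, B), bruteHausdorff(A, B))
    }
})

test_that("distance matrices are symmetric with the right index", {
    mkCloud <- function(pts, sb, sym) new("StateCloud", points = pts,
        timeIndices = seq_len(nrow(pts)), subject = sb,
        symbol = as.integer(sym))
    c1 <- mkCloud(rbind(c(1, 0)), "a", 1)
    c2 <- mkCloud(rbind(c(0, 1)), "a", 2)
    c3 <- mkCloud(rbind(c(1, 1) / sqrt(2)), "b", 1)
    D <- hausdorffMatrix(list(c1, c2, c3))
    dm <- hausdorffValues(D)
    expect_equal(diag(dm), rep(0, 3))
    expect_equal(dm[1, 2], 1)
    expect_equal(dm[1, 3], 1 - 1 / sqrt(2))
    expect_equal(dm[2, 3], 1 - 1 / sqrt(2))
    expect_identical(dm, t(dm))
    expect_equal(hausdorffIndex(D)$subject, c("a", "a", "b"))
    # one cloud: 1 x 1 zero matrix
    expect_equal(hausdorffValues(hausdorffMatrix(list(c1))),
                 matrix(0, 1, 1))
    # identical clouds: off-diagonal zero
    expect_equal(hausdorffValues(hausdorffMatrix(list(c1, c1)))[1, 2], 0)
})

test_that("threshold clustering follows the grammar over pooled indices", {
    mkD <- function(m, subjects) {
        idx <- data.frame(subject = subjects,
                          symbol = rep(1L, length(subjects)))
        new("HausdorffMatrix", dist = m, index = idx)
    }
    # pairs (1,3) and (2,4) below theta
    m <- matrix(1, 4, 4); diag(m) <- 0
    m[1, 3] <- m[3, 1] <- 0.1
    m[2, 4] <- m[4, 2] <- 0.1
    cl <- clusterStates(mkD(m, letters[1:4]), theta = 0.5)
    expect_equal(clusterLabels(cl)$cluster, c(1L, 2L, 1L, 2L))
    expect_equal(nClusters(cl), 2L)
    # theta below all distances: singletons; above all: one cluster
    expect_equal(nClusters(clusterStates(mkD(m, letters[1:4]), 0.05)), 4L)
    expect_equal(nClusters(clusterStates(mkD(m, letters[1:4]), 1.5)), 1L)
    expect_error(clusterStates(mkD(m, letters[1:4]), 0), "positive")
})

test_that("cluster count is non-increasing in theta", {
    set.seed(13)
    clouds <- lapply(1:8, function(i)
        new("StateCloud", points = randomUnitCloud(6, 4),
            timeIndices = 1:6, subject = sprintf("s%d", (i + 1) %/% 2),
            symbol = as.integer(i)))
    D <- hausdorffMatrix(clouds)
    counts <- vapply(seq(0.05, 2.0, by = 0.05), function(th)
        nClusters(clusterStates(D, th)), integer(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("pooling order changes cluster ids but not memberships", {
    set.seed(31)
    centers <- randomUnitCloud(2, 6)
    clouds <- lapply(1:6, function(i) {
        ctr <- centers[(i %% 2) + 1, ]
        pts <- matrix(ctr, 5, 6, byrow = TRUE) +
            matrix(rnorm(5 * 6, sd = 0.02), 5, 6)
        pts <- pts / sqrt(rowSums(pts^2))
        new("StateCloud", points = pts, timeIndices = 1:5,
            subject = sprintf("s%d", i), symbol = 1L)
    })
    partitionOf <- function(cl) {
        lab <- clusterLabels(cl)
        split(lab$subject, lab$cluster) |> lapply(sort) |>
            (\(x) unname(x[order(vapply(x, `[`, "", 1))]))()
    }
    p1 <- partitionOf(clusterStates(hausdorffMatrix(clouds), 0.5))
    perm <- c(4, 2, 6, 1, 5, 3)
    p2 <- partitionOf(clusterStates(hausdorffMatrix(clouds[perm]), 0.5))
    expect_identical(p1, p2)
})

test_that("coverage report flags shared and private clusters", {
    lab <- data.frame(subject = c("a", "a", "b", "b"),
                      symbol = c(1L, 2L, 1L, 2L),
                      cluster = c(1L, 2L, 1L, 2L))
    full <- new("EnsembleClustering", labels = lab, theta = 0.5,
                nClusters = 2L)
    cov <- coverageReport(full)
    expect_true(cov$fullCoverage)
    expect_equal(cov$clusterTable$nSubjects, c(2L, 2L))
    lab$cluster <- c(1L, 2L, 1L, 3L)   # cluster 2 and 3 private
    priv <- new("EnsembleClustering", labels = lab, theta = 0.5,
                nClusters = 3L)
    expect_false(coverageReport(priv)$fullCoverage)
})

test_that("theta search reports the minimal full-coverage clustering", {
    set.seed(17)
    centers <- rbind(c(1, rep(0, 7)), c(-1, rep(0, 7)))
    clouds <- list()
    for (sb in c("a", "b", "c")) for (k in 1:2) {
        pts <- matrix(centers[k, ], 4, 8, byrow = TRUE) +
            matrix(rnorm(4 * 8, sd = 0.03), 4, 8)
        pts <- pts / sqrt(rowSums(pts^2))
        clouds[[length(clouds) + 1L]] <- new("StateCloud", points = pts,
            timeIndices = 1:4, subject = sb, symbol = as.integer(k))
    }
    D <- hausdorffMatrix(clouds)
    sel <- selectTheta(D, seq(0.05, 1.5, by = 0.05))
    expect_false(is.na(sel$theta))
    best <- clusterStates(D, sel$theta)
    expect_equal(nClusters(best), 2L)
    expect_true(coverageReport(best)$fullCoverage)
})

test_that("ensemble relabeling rewrites symbols with cluster ids", {
    lab <- data.frame(subject = c("a", "a", "b"),
                      symbol = c(1L, 4L, 1L),
                      cluster = c(1L, 2L, 1L))
    cl <- new("EnsembleClustering", labels = lab, theta = 0.5,
              nClusters = 2L)
    seqs <- list(a = c(1L, 0L, 4L, 1L), b = c(0L, 1L, 1L, 0L))
    raster <- relabelEnsembleSequences(seqs, cl)
    expect_equal(raster["a", ], c(1L, 0L, 2L, 1L))
    expect_equal(raster["b", ], c(0L, 1L, 1L, 0L))
    # identity clustering leaves sequences unchanged
    labId <- data.frame(subject = c("a", "b"), symbol = c(1L, 1L),
                        cluster = c(1L, 1L))
    clId <- new("EnsembleClustering", labels = labId, theta = 0.5,
                nClusters = 1L)
    seqs2 <- list(a = c(1L, 1L, 0L), b = c(0L, 1L, 1L))
    r2 <- relabelEnsembleSequences(seqs2, clId)
    expect_equal(unname(r2["a", ]), c(1L, 1L, 0L))
    # unknown (subject, symbol) pair is a consistency error
    seqs3 <- list(a = c(1L, 9L, 0L), b = c(0L, 1L, 1L))
    expect_error(relabelEnsembleSequences(seqs3, clId), "no cluster")
})
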