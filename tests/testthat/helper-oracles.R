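# Independent oracles and random-case generators shared across tests.

# Map every node to the minimal index of its connected component, using
# igraph as an implementation-independent graph traversal.
componentMinOracle <- function(adj) {
    g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    mins <- tapply(seq_along(comp), comp, min)
    as.integer(mins[comp])
}

# Random symmetric logical matrix with unit diagonal (a recurrence plot
# shape), with edge density drawn per matrix.
randomRecurrenceMatrix <- function(nT, density = runif(1, 0.002, 0.2)) {
    m <- matrix(runif(nT * nT) < density, nT, nT)
    m <- m | t(m)
    diag(m) <- TRUE
    m
}

# Double-loop brute-force Hausdorff distance over cosine distances.
bruteHausdorff <- function(A, B) {
    dAB <- apply(A, 1L, function(x)
        min(apply(B, 1L, function(y) 1 - sum(x * y))))
    dBA <- apply(B, 1L, function(y)
        min(apply(A, 1L, function(x) 1 - sum(x * y))))
    max(max(dAB), max(dBA))
}

randomUnitCloud <- function(n, m) {
    pts <- matrix(rnorm(n * m), n, m)
    pts / sqrt(rowSums(pts^2))
}

# Random column-stochastic transition model of n states; with
# probability 1/2 the state set includes the transient label 0.
randomTransitionModel <- function(n) {
    P <- matrix(runif(n * n), n, n)
    # sprinkle structural zeros so renormalized rows/columns can be empty
    P[runif(n * n) < 0.3] <- 0
    for (j in seq_len(n)) {
        tot <- sum(P[, j])
        if (tot == 0) P[j, j] <- 1 else P[, j] <- P[, j] / tot
    }
    states <- if (n > 1L && runif(1) < 0.5) c(0L, seq_len(n - 1L))
              else seq_len(n)
    new("TransitionModel", probs = P, states = states)
}

# Two tight antipodal clusters bridged by short transients: ground truth
# for ball-size optimization (complexity 2).
twoClusterTrajectory <- function(nPerCluster = 60, m = 8, sigma = 0.02,
                                 seed = 7) {
    set.seed(seed)
    c1 <- c(1, rep(0, m - 1))
    c2 <- -c1
    rows <- list()
    for (rep in 1:3) {
        for (k in seq_len(nPerCluster / 3))
            rows[[length(rows) + 1L]] <- c1 + rnorm(m, sd = sigma)
        rows[[length(rows) + 1L]] <- rnorm(m)   # lone transient sample
        for (k in seq_len(nPerCluster / 3))
            rows[[length(rows) + 1L]] <- c2 + rnorm(m, sd = sigma)
        rows[[length(rows) + 1L]] <- rnorm(m)
    }
    v <- do.call(rbind, rows)
    normalizeTrajectory(v, mode = "unit")
}
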