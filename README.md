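# MetastableRSA

Recurrence structure analysis (RSA) for multivariate time series that
dwell in metastable states: resting-state fMRI module averages, EEG
band power, or any recording whose trajectory lingers in restricted
regions of state space before moving on. The package segments such
trajectories into metastable states and transients, selects the
segmentation scale by a Markov criterion, pools states across subjects,
and maps representative states onto labeled region spaces. It is aimed
at researchers who have module-averaged, time-ordered recordings (one
row per time point, one column per module) and want a symbolic,
Markov-interpretable description of their dynamics.

## The method

A trajectory is normalized to the unit hypersphere (optionally
z-scoring each module first) and compared by the cosine distance
`d(x, y) = 1 − x·y`. The recurrence plot

    R_ij = 1  iff  d(x_i, x_j) < ε

induces a rewriting grammar on time indices (every recurrent pair
`i > j` rewrites symbol `i` to `j`); its fixed point labels each time
point with the minimal time index of its recurrence class. Classes with
fewer than `minDwell` occurrences become the transient (label 0). The
ball size ε is chosen by maximizing the Markov utility

    u(ε) = [ tr P(ε) + h_r(ε) + h_c(ε) ] / (n + 2)

where `P` is the column-stochastic transition matrix of the symbolic
sequence, and `h_r`, `h_c` are normalized entropies of the renormalized
transitions into and out of the transient state — a maximally
metastable Markov state model. The number of metastable states
`n(ε*) − 1` is the segmentation complexity.

For an ensemble, metastable state clouds of all subjects are compared
by the max–min Hausdorff distance under the cosine metric; thresholding
at θ (study default 0.8) and reapplying the grammar yields ensemble
state clusters, a subjects × time cluster raster, and coverage
statistics. Each cluster is summarized by its max-norm representative
`x* = argmax ‖x‖∞` and projected onto K labeled regions through a
mixing matrix, `y* = M x*`.

Ground-truthed generators are first-class components: a metastable
switching surrogate with the sampling shape of resting-state module
averages (T ≈ 1200, M ∈ [3, 100]), and minimal simulators of three
canonical switching mechanisms — slow–fast hysteresis, a periodically
swept bistable double well, and a stochastic robust heteroclinic cycle
on the 3-sphere.

## Worked example

```r
library(MetastableRSA)

ens <- generateSwitchingEnsemble(switchingConfig(seed = 42),
                                 nSubjects = 4)
cfg <- pipelineConfig(normalization = "unit")
res <- lapply(names(ens$trajectories), function(sb)
    runSubjectPipeline(ens$trajectories[[sb]], cfg, subject = sb))
names(res) <- names(ens$trajectories)

sapply(res, function(r) r$report$complexity)
#> subject01 subject02 subject03 subject04
#>         3         3         3         3
```

Each subject's trajectory (1200 samples, 40 modules, three shared
states with mean dwell 40 samples and noise σ = 0.05) is segmented into
exactly the 3 generated metastable states; the recovered labels agree
with the generating labels at adjusted Rand index ≥ 0.99 on the
non-transient samples. Pooling a 4-subject ensemble generated from two
strongly anti-correlated shared centers and clustering at θ = 0.8:

```r
ens2 <- generateSwitchingEnsemble(
    switchingConfig(nStates = 2L, minCenterAngle = 2 * pi / 3,
                    seed = 43), nSubjects = 4)
res2 <- lapply(names(ens2$trajectories), function(sb)
    runSubjectPipeline(ens2$trajectories[[sb]], cfg, subject = sb))
names(res2) <- names(ens2$trajectories)
ep <- runEnsemblePipeline(res2, pipelineConfig(normalization = "unit",
                                               theta = 0.8))
ep$clustering
#> EnsembleClustering: 2 cluster(s) over 8 cloud(s) at theta = 0.8
ep$coverage$fullCoverage
#> [1] TRUE
```

The two clusters cover all four subjects — a bistable ensemble
segmentation. `runEnsemblePipeline()` also returns the subjects × time
raster and, when a mixing matrix is supplied (`readMixingMatrix()` or
`syntheticMixingMatrix()` with 45 labeled regions for the
anatomical-atlas-like case), per-cluster projection profiles ranked by
`rankRegions()`.

The simulators run the same analysis end to end, e.g.

```r
sf <- runSubjectPipeline(simulateSlowFast(),
                         pipelineConfig(grid = "log", minDwell = 5L))
sf$report$complexity
#> [1] 2
```

A thin command-line front end with subcommands `simulate`, `segment`,
`sweep`, `ensemble` and `project` is installed at
`system.file("cli", "rsa.R", package = "MetastableRSA")`; it reads and
writes plain TSV and exits 0/2/3 on success/input error/contract
violation.

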