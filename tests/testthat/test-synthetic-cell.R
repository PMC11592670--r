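test_that("surface sampling is reproducible and respects the hard core", {
    p1 <- sampleSurfacePoints(500, seed = 7)
    p2 <- sampleSurfacePoints(500, seed = 7)
    expect_identical(p1, p2)
    expect_false(identical(p1, sampleSurfacePoints(500, seed = 8)))

    # points lie on the ellipsoid surface (unit implicit equation)
    ax <- c(35, 7.1, 7.1) * 1000
    q <- sweep(p1, 2, ax, "/")
    expect_equal(rowSums(q^2), rep(1, 500), tolerance = 1e-9)

    # Matern II thinning guarantees the minimum spacing
    ph <- sampleSurfacePoints(800, process = "hardcore",
                              hardcoreRadius = 390, seed = 3)
    expect_gte(min(nearestNeighborDistances(ph)), 390)

    # infeasible packing errors with the achievable maximum
    expect_error(sampleSurfacePoints(5000, semiAxes = c(5, 3, 3),
                                     process = "hardcore",
                                     hardcoreRadius = 800, seed = 1),
                 "hard-core radius too large")
})

test_that("the default spec reproduces the measured spatial regime", {
    # mean NND of the default hard-core surface pattern ~ 639 nm
    mn <- mean(vapply(1:3, function(s) {
        p <- sampleSurfacePoints(2285, process = "hardcore",
                                 hardcoreRadius = 390, seed = s)
        mean(nearestNeighborDistances(p))
    }, numeric(1)))
    expect_lt(abs(mn - 638.62) / 638.62, 0.03)
})

test_that("size draws follow the aggregated mixture ground truth", {
    x <- sampleSizes(1e5, seed = 31)
    agg <- aggMixture()
    mixMean <- sum(agg$weight * agg$shape / agg$rate)
    expect_equal(mean(x), mixMean, tolerance = 0.02)
    comp <- attr(x, "component")
    expect_setequal(unique(comp), 1:2)
    expect_equal(mean(comp == 1L), 0.16, tolerance = 0.05)
    # component-2 draws have the printed 95th percentile
    q95 <- quantile(x[comp == 2L], 0.95, names = FALSE)
    expect_equal(q95, 0.478, tolerance = 0.02 * 0.478)
    # degenerate weight: all draws from component 2
    x2 <- sampleSizes(100, list(shape = c(4.35, 2.22),
                                rate = c(125, 10.64), weight = 0),
                      seed = 1)
    expect_true(all(attr(x2, "component") == 2L))
})

test_that("synthetic cells are self-describing and reproducible", {
    spec <- syntheticCellSpec(nClusters = 300, nNoisePoints = 4,
                              nExtremeOutliers = 2, seed = 12)
    cell <- makeSyntheticCell(spec)
    # noise points add rows; extreme outliers inflate existing volumes
    expect_identical(nClusters(cell$clusterSet), 304L)
    expect_identical(nrow(cell$truth), 304L)
    expect_identical(sum(cell$truth$role == "noise"), 4L)
    expect_identical(sum(cell$truth$role == "size_outlier"), 2L)
    big <- cell$truth$role == "size_outlier"
    expect_true(all(clusters(cell$clusterSet)$volume[big] > 1))
    md <- cell$clusterSet@metadata
    expect_identical(md$seed, 12L)
    expect_identical(md$spec$nClusters, 300L)
    cell2 <- makeSyntheticCell(spec)
    expect_identical(clusters(cell$clusterSet), clusters(cell2$clusterSet))
})

test_that("clean fixtures are retained (fully for regular, ~fully for Poisson)", {
    # a quasi-regular (jittered-lattice) surface pattern with uniform
    # spacing guarantees every cluster is core: exact 100% retention
    spec <- syntheticCellSpec(semiAxes = c(8, 8, 8), nClusters = 1500,
                              pointProcess = "lattice", nNoisePoints = 0,
                              nExtremeOutliers = 0, seed = 5)
    cs <- extractCell(makeSyntheticCell(spec)$clusterSet)
    expect_true(all(clusters(cs)$in_cell))
    # a Poisson surface always leaves a small density-invariant fraction
    # of sub-core points; retention stays high but is never guaranteed
    for (s in 1:3) {
        spec <- syntheticCellSpec(semiAxes = c(12, 5, 5), nClusters = 1500,
                                  pointProcess = "poisson",
                                  nNoisePoints = 0, nExtremeOutliers = 0,
                                  seed = s)
        cs <- extractCell(makeSyntheticCell(spec)$clusterSet)
        expect_gt(mean(clusters(cs)$in_cell), 0.9)
    }
})

test_that("planted noise points are recovered by the full pipeline", {
    cell <- makeSyntheticCell(syntheticCellSpec(
        semiAxes = c(15, 6, 6), nClusters = 900, nNoisePoints = 10,
        nExtremeOutliers = 3, seed = 21))
    an <- suppressWarnings(
        analyzeCell(cell$clusterSet, mixtureComponents = 2))
    df <- clusters(an@clusterSet)
    noise <- cell$truth$role == "noise"
    expect_true(all(!df$in_cell[noise]))
    # the vast majority of true cell clusters is kept
    expect_gt(mean(df$in_cell[!noise]), 0.85)
    # planted volume outliers that survive the density filter are fenced
    # out of the size statistics
    big <- cell$truth$role == "size_outlier" & df$in_cell
    expect_gt(sum(big), 0)
    expect_true(all(df$size_outlier[big]))
})

test_that("ground-truth labels validate the mixture classification", {
    x <- sampleSizes(5000, seed = 33)
    fit <- fitGammaMixture(as.numeric(x), 2)
    cmp <- components(fit)
    post1 <- cmp$weight[1] * dgamma(x, cmp$shape[1], rate = cmp$rate[1])
    post2 <- cmp$weight[2] * dgamma(x, cmp$shape[2], rate = cmp$rate[2])
    pred <- ifelse(post1 > post2, 1L, 2L)
    expect_gt(mean(pred == attr(x, "component")), 0.8)
})

test_that("end-to-end pipeline is stable on clean Poisson fixtures", {
    for (s in 1:3) {
        cell <- makeSyntheticCell(syntheticCellSpec(
            semiAxes = c(15, 6, 6), nClusters = 1200,
            pointProcess = "poisson", nNoisePoints = 0,
            nExtremeOutliers = 0, seed = s))
        an <- analyzeCell(cell$clusterSet, mixtureComponents = 2)
        expect_identical(an@geometry@metadata$nComponents, 1L)
        b <- an@summary$b
        expect_true(is.finite(b))
        expect_gt(b, 0.3)
        expect_lt(b, 1.7)
    }
})
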