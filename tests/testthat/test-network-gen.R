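test_that("generated positions satisfy the basic contract", {
    dom <- cruDomain(300)
    for (step in c(0L, 10L)) {
        p <- generatePositions(300, dom, step = step, seed = 3)
        expect_identical(dim(p), c(300L, 2L))
        expect_true(all(p[, 1] >= 0 & p[, 1] <= dom$width))
        expect_true(all(p[, 2] >= 0 & p[, 2] <= dom$height))
    }
    # same seed, same config: bit-identical
    expect_identical(generatePositions(300, dom, step = 10, seed = 3),
                     generatePositions(300, dom, step = 10, seed = 3))
    expect_false(identical(generatePositions(300, dom, step = 10, seed = 4),
                           generatePositions(300, dom, step = 10, seed = 3)))
})

test_that("mean NND is non-decreasing along the repulsion schedule", {
    for (s in 1:3) {
        tr <- repulsionTrajectory(600, seed = s)
        expect_length(tr, 101L)
        expect_true(all(diff(tr) >= 0))
        # the crystal-like end state is markedly more spaced out
        expect_gt(tr[101], 1.4 * tr[1])
    }
})

test_that("repulsion reduces the NND coefficient of variation", {
    net0 <- generateNetwork(600, step = 0, seed = 2)
    net100 <- generateNetwork(600, step = 100, seed = 2)
    cv <- function(x) sd(x) / mean(x)
    expect_lt(cv(networkNnd(net100)), 0.5 * cv(networkNnd(net0)))
})

test_that("calibrateStep finds the step matching a target mean NND", {
    tr <- repulsionTrajectory(500, seed = 11)
    # self-consistency: targeting the value observed at a step returns it
    s <- calibrateStep(tr[31], 500, seeds = 11)
    expect_lte(abs(s - 30L), 1L)
    # achieved mean NND within 5% of an interior target
    target <- (tr[1] + tr[101]) / 2
    s2 <- calibrateStep(target, 500, seeds = 11)
    expect_lt(abs(attr(s2, "meanNnd") - target) / target, 0.05)
    expect_true(s2 > 0 && s2 < 100)
    # out-of-range target errors with the achievable range
    expect_error(calibrateStep(10 * tr[101], 500, seeds = 11),
                 "achievable range")
})

test_that("the experimental mean NND is reached at an intermediate step", {
    # density matched to the measured average (2285 clusters / 2505 um^2);
    # the measured mean NND of 638.62 nm must sit strictly inside the
    # schedule, between the uniform-random and crystal-like extremes
    s <- calibrateStep(638.62, 1000, seeds = 1:2)
    expect_true(s > 0 && s < 100)
    expect_lt(abs(attr(s, "meanNnd") - 638.62) / 638.62, 0.05)
})

test_that("RyR counts conserve the total exactly in every mode", {
    # identical mode: every CRU gets 48
    counts <- assignSizes(100, "identical")
    expect_identical(counts, rep.int(48L, 100L))
    expect_identical(sum(counts), 4800L)
    expect_error(assignSizes(100, "identical", totalRyr = 4000L),
                 "48")

    # realistic mode from the mixture: exact conservation, minimum 1
    for (s in 1:5) {
        counts <- assignSizes(500, "realistic", totalRyr = 48L * 500L,
                              sizeDistribution = aggMixture(), seed = s)
        expect_identical(sum(counts), 48L * 500L)
        expect_true(all(counts >= 1L))
    }
    # empirical volume vector works too
    set.seed(3)
    vols <- rgamma(1000, 2.2, rate = 10)
    counts <- assignSizes(200, "realistic", totalRyr = 9600L,
                          sizeDistribution = vols, seed = 4)
    expect_identical(sum(counts), 9600L)

    # degenerate point-mass distribution: everyone gets the mean size
    counts <- assignSizes(50, "realistic", totalRyr = 2400L,
                          sizeDistribution = rep(0.2, 10), seed = 5)
    expect_identical(counts, rep.int(48L, 50L))

    expect_error(assignSizes(10, "realistic", totalRyr = 5L,
                             sizeDistribution = aggMixture()),
                 "infeasible")
})

test_that("volumeToRyr maps the mean volume to 48 and scales linearly", {
    mu <- 0.18
    expect_identical(volumeToRyr(mu, mu), 48L)
    expect_identical(volumeToRyr(2 * mu, mu), 96L)
    expect_identical(volumeToRyr(1e-6, mu), 1L)   # clamped at 1
    # the aggregated mixture mean maps to 48; the large-cluster threshold
    # (component-2 95th percentile) maps well above it
    agg <- aggMixture()
    mixMean <- sum(agg$weight * agg$shape / agg$rate)
    expect_identical(volumeToRyr(mixMean, mixMean), 48L)
    expect_gt(volumeToRyr(0.478, mixMean), 48L)
})

test_that("generateNetwork bundles a valid, reproducible network", {
    net <- generateNetwork(400, step = 5, seed = 21, mode = "realistic",
                           sizeDistribution = aggMixture())
    expect_s4_class(net, "CRUNetwork")
    expect_identical(sum(ryrCounts(net)), totalRyr(net))
    expect_identical(repulsionStep(net), 5L)
    expect_gt(meanNnd(net), 0)
    net2 <- generateNetwork(400, step = 5, seed = 21, mode = "realistic",
                            sizeDistribution = aggMixture())
    expect_identical(positions(net), positions(net2))
    expect_identical(ryrCounts(net), ryrCounts(net2))
})
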