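test_that("the mixture density behaves like its closed forms", {
    # degenerate single-component mixture equals the plain Gamma density
    x <- seq(0.01, 2, length.out = 50)
    one <- list(shape = 3, rate = 10, weight = 1)
    expect_equal(dGammaMixture(x, one), dgamma(x, 3, rate = 10))
    # Gamma(1,1) tends to 1 at the origin (exponential)
    expect_equal(dGammaMixture(1e-9, list(shape = 1, rate = 1, weight = 1)),
                 1, tolerance = 1e-6)
    expect_error(dGammaMixture(c(0.5, -1), one), "positive")
    # normalization of the aggregated-parameter mixture
    int <- integrate(dGammaMixture, 0, Inf, fit = aggMixture(),
                     rel.tol = 1e-10)
    expect_equal(int$value, 1, tolerance = 1e-6)
})

test_that("moments initialization splits at the median sensibly", {
    set.seed(1)
    x <- rgamma(500, shape = 4, rate = 10)
    init <- momentsInit(x)
    expect_true(all(is.finite(unlist(init[c("shape", "rate")]))))
    expect_true(all(init$shape > 0) && all(init$rate > 0))

    # well-separated bimodal sample: lower half mean < upper half mean
    set.seed(2)
    y <- c(rgamma(300, 20, rate = 400), rgamma(300, 50, rate = 100))
    init2 <- momentsInit(y)
    expect_lt(init2$shape[1] / init2$rate[1], init2$shape[2] / init2$rate[2])

    # a scaled copy as the upper half: identical shapes (scale-free),
    # rates in the inverse scale ratio
    h <- sort(rgamma(100, 4, 10))
    init3 <- momentsInit(c(h, h * 100))
    expect_equal(init3$shape[1], init3$shape[2])
    expect_equal(init3$rate[1], 100 * init3$rate[2])

    expect_error(momentsInit(c(1, 2)), "at least 4")
    expect_error(momentsInit(c(-1, 1, 2, 3)), "positive")
})

test_that("bounded MLE recovers the aggregated parameters from 70k draws", {
    truth <- aggMixture()
    x <- rGammaMixture(70000, truth, seed = 101)
    fit <- fitGammaMixture(as.numeric(x), 2)
    cmp <- components(fit)
    expect_true(fit@converged)
    rel <- abs(c(cmp$shape[1] / truth$shape[1],
                 cmp$rate[1] / truth$rate[1],
                 cmp$shape[2] / truth$shape[2],
                 cmp$rate[2] / truth$rate[2],
                 cmp$weight[1] / truth$weight[1]) - 1)
    expect_true(all(rel < 0.10))
})

test_that("the fit is exchangeable and respects likelihood nesting", {
    set.seed(4)
    x <- rgamma(3000, shape = 3, rate = 12)
    f1 <- fitGammaMixture(x, 1)
    f2 <- fitGammaMixture(x, 2)
    # adding a component can only improve the likelihood
    expect_gte(logLik(f2), logLik(f1) - 1e-6 * abs(logLik(f1)))
    # permuting the input leaves the fit unchanged
    set.seed(5)
    fp <- fitGammaMixture(sample(x), 2)
    expect_equal(components(fp), components(f2), tolerance = 1e-5)
    expect_error(fitGammaMixture(c(x, -1), 2), "positive")
})

test_that("BIC selects the generating component count", {
    set.seed(6)
    xs <- rgamma(5000, shape = 3.5, rate = 15)
    fitS <- selectComponents(xs, 1:2)
    expect_identical(nComponents(fitS), 1L)
    expect_true(is.finite(mixtureBIC(fitS)))

    xm <- rGammaMixture(8000, aggMixture(), seed = 7)
    fitM <- selectComponents(as.numeric(xm), 1:2)
    expect_identical(nComponents(fitM), 2L)
    tab <- attr(fitM, "bicTable")
    expect_identical(nrow(tab), 2L)
    expect_true(all(is.finite(tab$bic)))
})

test_that("component statistics match closed forms and Monte Carlo", {
    # closed forms
    fit <- new("GammaMixtureFit",
               components = data.frame(shape = c(6, 1), rate = c(2, 1),
                                       weight = c(0.5, 0.5)),
               logLik = 0, bic = 0, nObs = 10L, converged = TRUE,
               metadata = list())
    st <- componentStats(fit, 1)
    expect_equal(st$excessKurtosis, 1.0)
    expect_equal(st$mean, 3)
    expect_equal(st$sd, sqrt(6) / 2)
    expect_equal(qgamma(0.5, 1, 1), log(2), tolerance = 1e-6)

    # Monte Carlo agreement within 1%
    set.seed(9)
    draws <- rgamma(1e6, shape = 2.22, rate = 10.64)
    st2 <- componentStats(new("GammaMixtureFit",
        components = data.frame(shape = 2.22, rate = 10.64, weight = 1),
        logLik = 0, bic = 0, nObs = 10L, converged = TRUE,
        metadata = list()), 1)
    expect_equal(st2$mean, mean(draws), tolerance = 0.01)
    expect_equal(st2$sd, sd(draws), tolerance = 0.01)
    expect_equal(st2$percentile95, quantile(draws, 0.95, names = FALSE),
                 tolerance = 0.01)
})

test_that("the large-cluster threshold flags the upper tail monotonically", {
    x <- rGammaMixture(20000, aggMixture(), seed = 12)
    fit <- fitGammaMixture(as.numeric(x), 2)
    thr <- largeCruThreshold(fit)
    # the 95th percentile sits above the component mean
    expect_gt(thr, componentStats(fit, 2)$mean)
    # flags are monotone in volume
    df <- data.frame(id = 1:100, x = runif(100), y = runif(100),
                     z = runif(100), volume = sort(runif(100, 0.01, 1)))
    cs <- flagLargeCRUs(ClusterSet(df), fit)
    fl <- clusters(cs)$large_cru
    expect_true(all(diff(as.integer(fl)) >= 0))
    expect_identical(fl, df$volume >= thr)

    f1 <- fitGammaMixture(rgamma(500, 3, 10), 1)
    expect_error(largeCruThreshold(f1), "two-component")
})
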