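test_that("nearest-neighbor distances match hand examples and the brute-force oracle", {
    expect_equal(nearestNeighborDistances(cbind(c(0, 1), 0, 0)), c(1, 1))
    expect_equal(nearestNeighborDistances(cbind(c(0, 1, 3), 0, 0)),
                 c(1, 1, 2))
    expect_error(nearestNeighborDistances(cbind(1, 1, 1)), "at least 2")
    expect_warning(
        nearestNeighborDistances(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))),
        "duplicate")
    for (s in 1:3) {
        set.seed(s)
        n <- c(50, 200, 500)[s]
        pts <- matrix(runif(3 * n, 0, 1000), n, 3)
        expect_equal(nearestNeighborDistances(pts), bruteNnd(pts))
    }
})

test_that("scaled MAD uses the normal-consistency constant", {
    expect_equal(madScaleConstant(), 1.4826, tolerance = 1e-4)
    expect_equal(scaledMad(1:5), 1.4826, tolerance = 1e-4)
    expect_identical(scaledMad(rep(3.7, 10)), 0)
    expect_error(scaledMad(numeric(0)), "empty")
    # approximates the SD of normal data
    set.seed(1)
    x <- rnorm(2e5)
    expect_equal(scaledMad(x), 1, tolerance = 0.02)
    # agrees with the base mad() implementation (which hard-codes 1.4826)
    set.seed(2)
    y <- rexp(101)
    expect_equal(scaledMad(y), mad(y), tolerance = 1e-5)
})

test_that("DBSCAN epsilon is median + 3 scaled MADs of the NNDs", {
    p <- dbscanEpsilon(1:5)
    expect_equal(p$epsilon, 3 + 3 * 1.4826, tolerance = 1e-3)
    expect_identical(p$minSamples, 3L)
    # zero spread: epsilon collapses to the common distance
    expect_equal(dbscanEpsilon(rep(7, 9))$epsilon, 7)
    # epsilon responds to the MAD, not to the extremes directly
    a <- c(1, 2, 3, 4, 5)
    b <- c(1, 2, 3, 4, 500)   # same median, same MAD
    expect_equal(dbscanEpsilon(a)$epsilon, dbscanEpsilon(b)$epsilon)
})

test_that("DBSCAN separates a dense blob from isolated outliers", {
    # pairwise-dense blob: any epsilon above its diameter keeps it whole
    pts <- blobWithOutliers(nBlob = 500, nOut = 5, seed = 1)
    db <- runDBSCAN(pts, eps = 500, minPts = 3)
    expect_identical(db$type[501:505], rep("noise", 5))
    expect_true(all(db$cluster[1:500] == db$cluster[1]))
    expect_true(db$cluster[1] > 0)

    # all mutually within eps: one cluster, all core
    tight <- matrix(rnorm(30, sd = 0.1), 10, 3)
    db2 <- runDBSCAN(tight, eps = 10, minPts = 3)
    expect_true(all(db2$type == "core"))
    expect_true(all(db2$cluster == 1L))
})

test_that("DBSCAN agrees with the neighbor-counting oracle", {
    for (s in 1:4) {
        set.seed(s)
        n <- 150 + 50 * s
        pts <- rbind(matrix(rnorm(3 * n, sd = 50), n, 3),
                     matrix(rnorm(60, sd = 2000), 20, 3))
        eps <- 3 * 50 / n^(1 / 3) * 4
        got <- runDBSCAN(pts, eps, 3)
        want <- bruteDbscan(pts, eps, 3)
        expect_identical(got$type, want$type)
        expect_true(all((got$cluster == 0) == (want$cluster == 0)))
        # identical partition of the core points (labels may be permuted;
        # a border point between two clusters may legitimately attach to
        # either, so only cores are compared)
        core <- want$type == "core"
        tab <- table(got$cluster[core], want$cluster[core])
        expect_true(all(colSums(tab > 0) == 1) && all(rowSums(tab > 0) == 1))
    }
})

test_that("extractCell keeps the largest density cluster only", {
    big <- blobWithOutliers(300, 0, seed = 31)
    small <- blobWithOutliers(100, 0, seed = 32) +
        matrix(rep(c(1e5, 0, 0), each = 100), 100, 3)
    df <- data.frame(id = 1:400, x = c(big[, 1], small[, 1]),
                     y = c(big[, 2], small[, 2]),
                     z = c(big[, 3], small[, 3]), volume = 0.1)
    cs <- extractCell(ClusterSet(df),
                      params = list(epsilon = 1000, minSamples = 3L))
    flags <- clusters(cs)$in_cell
    expect_true(all(flags[1:300]))
    expect_false(any(flags[301:400]))
})

test_that("Tukey fences use interpolated quartiles and are idempotent", {
    v <- c(1:10, 100)
    tk <- tukeyFilter(v)
    # Q1 = 3.5, Q3 = 8.5, fences [-11.5, 23.5]
    expect_identical(tk$values, as.numeric(1:10))
    expect_identical(tk$mask, c(rep(TRUE, 10), FALSE))
    expect_length(tk$mask, length(v))

    # constant list: zero IQR, boundary values are inside the closed fence
    expect_true(all(tukeyFilter(rep(5, 8))$mask))

    # idempotence
    tk2 <- tukeyFilter(tk$values)
    expect_identical(tk2$values, tk$values)

    expect_warning(tukeyFilter(1:3), "fewer than 4")
})
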