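test_that("label volumes convert voxels to physical units exactly", {
    # single labeled voxel in a 3x3x3 grid
    arr <- array(0L, c(3, 3, 3))
    arr[2, 2, 2] <- 1L
    f <- tempfile(fileext = ".tif")
    tiff::writeTIFF(lapply(1:3, function(z) arr[, , z] / 65535), f,
                    bits.per.sample = 16)
    cs <- readLabelVolume(f, c(55.5, 55.5, 150))
    expect_equal(nClusters(cs), 1L)
    expect_equal(clusters(cs)$volume, 55.5 * 55.5 * 150 * 1e-9)
    expect_equal(clusters(cs)$volume, 4.6204e-4, tolerance = 1e-4)

    # two voxels of one label: centroid is the midpoint of voxel centers
    arr <- array(0L, c(3, 3, 3))
    arr[1, 1, 1] <- 7L   # (x=0, y=0, z=0)
    arr[1, 2, 1] <- 7L   # (x=55.5, y=0, z=0)
    tiff::writeTIFF(lapply(1:3, function(z) arr[, , z] / 65535), f,
                    bits.per.sample = 16)
    cs <- readLabelVolume(f, c(55.5, 55.5, 150))
    expect_equal(clusters(cs)$x, mean(c(0, 55.5)))
    expect_equal(clusters(cs)$y, 0)
    expect_equal(clusters(cs)$voxel_count, 2L)
})

test_that("volume equals voxel count x voxel volume on a random volume", {
    set.seed(42)
    arr <- array(sample(0:9, 1000, replace = TRUE), c(10, 10, 10))
    f <- tempfile(fileext = ".tif")
    tiff::writeTIFF(lapply(1:10, function(z) arr[, , z] / 65535), f,
                    bits.per.sample = 16)
    dims <- c(55.5, 55.5, 150)
    cs <- readLabelVolume(f, dims)
    df <- clusters(cs)
    # brute-force per-voxel count per label
    for (k in df$id) {
        cnt <- sum(arr == k)
        row <- df[df$id == k, ]
        expect_identical(row$voxel_count, cnt)
        expect_equal(row$volume, cnt * prod(dims) * 1e-9)
    }
    # order independence: permuting the label values gives the same table
    perm <- c(0, sample(1:9))
    arr2 <- array(perm[arr + 1L], dim(arr))
    tiff::writeTIFF(lapply(1:10, function(z) arr2[, , z] / 65535), f,
                    bits.per.sample = 16)
    df2 <- clusters(readLabelVolume(f, dims))
    df2$id <- match(df2$id, perm) - 1L
    df2 <- df2[order(df2$id), ]
    rownames(df) <- rownames(df2) <- NULL
    expect_equal(df2[, -1], df[, -1])
})

test_that("label volume loading rejects bad inputs", {
    f <- tempfile(fileext = ".tif")
    tiff::writeTIFF(matrix(0, 4, 4), f, bits.per.sample = 16)
    expect_error(readLabelVolume(f), "no nonzero labels")
})

test_that("cluster table CSV round-trips and validates its schema", {
    df <- data.frame(id = 1:3, x = c(0, 100.5, 500), y = c(1, 2, 3),
                     z = c(10, 20, 30), volume = c(0.1, 0.2, 0.15))
    cs <- ClusterSet(df)
    f <- tempfile(fileext = ".csv")
    writeClusterTable(cs, f)
    cs2 <- readClusterTable(f)
    expect_equal(nClusters(cs2), 3L)
    expect_equal(clusters(cs2)$volume, df$volume)
    expect_equal(centroids(cs2), centroids(cs))
    expect_false(any(clusters(cs2)$in_cell))

    # missing column names the column
    bad <- df[, c("id", "x", "y", "z")]
    utils::write.csv(bad, f, row.names = FALSE)
    expect_error(readClusterTable(f), "volume")

    # non-finite values are rejected
    df$volume[2] <- NA
    utils::write.csv(df, f, row.names = FALSE)
    expect_error(readClusterTable(f), "non-finite")
})

test_that("mesh OBJ round-trips with identical vertex and face counts", {
    set.seed(7)
    pts <- matrix(rnorm(3 * 60, sd = 1000), 60, 3)
    geom <- alphaShape(pts, Inf)
    f <- tempfile(fileext = ".obj")
    writeMeshOBJ(geom, f)
    mesh <- readMeshOBJ(f)
    expect_identical(nrow(mesh$vertices), nrow(meshVertices(geom)))
    expect_identical(nrow(mesh$faces), nrow(meshFaces(geom)))
    expect_equal(mesh$vertices, unname(meshVertices(geom)),
                 tolerance = 1e-5)
})

test_that("network JSON round-trips", {
    net <- generateNetwork(50, step = 3, seed = 9)
    f <- tempfile(fileext = ".json")
    writeNetworkJSON(net, f)
    net2 <- readNetworkJSON(f)
    expect_equal(positions(net2), unname(positions(net)))
    expect_identical(ryrCounts(net2), ryrCounts(net))
    expect_identical(totalRyr(net2), totalRyr(net))
    expect_identical(repulsionStep(net2), repulsionStep(net))
})

test_that("writeResults emits the full artifact set with 13 summary fields", {
    cell <- makeSyntheticCell(syntheticCellSpec(
        semiAxes = c(12, 5, 5), nClusters = 600, pointProcess = "poisson",
        nNoisePoints = 5, nExtremeOutliers = 2, seed = 3))
    an <- analyzeCell(cell$clusterSet)
    dir <- tempfile()
    paths <- writeResults(an, dir)
    expect_true(all(file.exists(paths)))
    summ <- utils::read.csv(paths[["summary"]])
    expect_identical(ncol(summ), 13L)
    expect_named(summ, c("surface_area", "volume", "n_clusters",
                         "nnd_mean", "nnd_sd", "size_mean", "size_sd",
                         "b", "alpha1", "beta1", "alpha2", "beta2", "pi"))
    expect_identical(nrow(utils::read.csv(paths[["clusters"]])),
                     nClusters(cell$clusterSet))
})
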