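# Independent brute-force oracles used across tests.

# O(n^2) nearest-neighbor distances by explicit per-point scan.
bruteNnd <- function(points) {
    n <- nrow(points)
    vapply(seq_len(n), function(i) {
        best <- Inf
        for (j in seq_len(n)) {
            if (j == i) next
            d <- sqrt(sum((points[i, ] - points[j, ])^2))
            if (d < best) best <- d
        }
        best
    }, numeric(1))
}

# Direct DBSCAN classification by neighbor counting: core points have
# >= minPts neighbors within eps (self included); clusters are connected
# components of the core-point graph; border points attach to a core's
# cluster; the rest is noise.
bruteDbscan <- function(points, eps, minPts) {
    n <- nrow(points)
    d <- unname(as.matrix(stats::dist(points)))
    nb <- d <= eps
    core <- unname(rowSums(nb) >= minPts)
    type <- ifelse(core, "core", "noise")
    labels <- integer(n)
    cl <- 0L
    for (i in which(core)) {
        if (labels[i]) next
        cl <- cl + 1L
        stack <- i
        while (length(stack)) {
            k <- stack[[1]]
            stack <- stack[-1]
            if (labels[k]) next
            labels[k] <- cl
            stack <- c(stack, setdiff(which(nb[k, ] & core), which(labels > 0)))
        }
    }
    for (i in which(!core)) {
        cores <- which(nb[i, ] & core)
        if (length(cores)) {
            labels[i] <- labels[cores[1]]
            type[i] <- "border"
        }
    }
    list(cluster = labels, type = type, core = core)
}

# Pairwise-dense blob (every pair closer than `diameter`) plus isolated
# far-away points: a fixture with a guaranteed DBSCAN answer for any
# epsilon between `diameter` and `farDist`.
blobWithOutliers <- function(nBlob, nOut, diameter = 200, farDist = 1e5,
                             seed = 1) {
    set.seed(seed)
    u <- matrix(rnorm(3 * nBlob), nBlob, 3)
    u <- u / sqrt(rowSums(u^2))
    blob <- u * (diameter / 2) * runif(nBlob)^(1 / 3)
    dirs <- matrix(rnorm(3 * nOut), nOut, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    far <- dirs * (farDist * seq(2, 2 + nOut - 1))
    rbind(blob, far)
}

# The aggregated two-component size mixture used as the study's ground
# truth throughout the tests.
aggMixture <- function() {
    list(shape = c(4.35, 2.22), rate = c(125, 10.64),
         weight = c(0.16, 0.84))
}
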