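#' Nearest-neighbor distances of a 3D point set
#'
#' Euclidean distance from each point to its nearest other point. Distances
#' are computed in the units of the input coordinates (nanometres throughout
#' this package). Coordinates must be distinct; coincident points produce a
#' zero distance and a warning.
#'
#' @param points numeric matrix (n x 3) of coordinates, or a
#'   [ClusterSet-class] (centroids are used).
#' @param chunk internal block size for the blocked all-pairs computation.
#' @return numeric vector of length n of nearest-neighbor distances.
#' @examples
#' pts <- cbind(c(0, 1, 3), 0, 0)
#' nearestNeighborDistances(pts)  # 1, 1, 2
#' @export
nearestNeighborDistances <- function(points, chunk = 1024L) {
    if (is(points, "ClusterSet")) points <- centroids(points)
    points <- .asPointMatrix(points)
    n <- nrow(points)
    if (n < 2) stop("need at least 2 points for nearest-neighbor distances")
    d <- numeric(n)
    for (start in seq.int(1L, n, by = chunk)) {
        idx <- start:min(start + chunk - 1L, n)
        d2 <- .crossDist2(points[idx, , drop = FALSE], points)
        d2[cbind(seq_along(idx), idx)] <- Inf
        d[idx] <- sqrt(apply(d2, 1, min))
    }
    if (any(d == 0))
        warning("duplicate coordinates: zero nearest-neighbor distance(s)")
    d
}

#' MAD scale constant for normal consistency
#'
#' The constant \eqn{c = -1 / (\sqrt{2}\,\mathrm{erfcinv}(3/2)) \approx
#' 1.4826} that makes the scaled median absolute deviation a consistent
#' estimator of the standard deviation for normally distributed data.
#' (Equivalently \eqn{1/\Phi^{-1}(3/4)}.)
#'
#' @return the scale constant, approximately 1.4826.
#' @export
madScaleConstant <- function() {
    # erfcinv(y) = -qnorm(y/2) / sqrt(2)
    erfcinv <- function(y) -stats::qnorm(y / 2) / sqrt(2)
    -1 / (sqrt(2) * erfcinv(3 / 2))
}

#' Scaled median absolute deviation
#'
#' \eqn{c \cdot \mathrm{median}(|A - \mathrm{median}(A)|)} with the normal
#' consistency constant \eqn{c \approx 1.4826}, so that for normal data the
#' result approximates the standard deviation.
#'
#' @param values numeric vector (non-empty).
#' @return the scaled MAD.
#' @examples
#' scaledMad(1:5)  # = 1.4826
#' @export
scaledMad <- function(values) {
    if (!length(values)) stop("scaledMad: empty input")
    madScaleConstant() * stats::median(abs(values - stats::median(values)))
}

#' Robust DBSCAN epsilon from nearest-neighbor distances
#'
#' The DBSCAN radius used to separate the cell's cluster network from
#' stray segmentation artifacts:
#' \eqn{\epsilon = \mathrm{median}(A) + 3\, c\, \mathrm{MAD}(A)} where A is
#' the set of nearest-neighbor distances and the MAD is scaled by
#' \eqn{c \approx 1.4826}. The median/MAD combination keeps \eqn{\epsilon}
#' robust against the extreme distances contributed by the very artifacts
#' being removed.
#'
#' @param nnds numeric vector of nearest-neighbor distances (nm).
#' @param minSamples minimum number of points (self included) in an
#'   epsilon-neighborhood for a core point; default 3.
#' @return list with elements \code{epsilon}, \code{minSamples} and the
#'   scale constant \code{c}.
#' @examples
#' dbscanEpsilon(1:5)$epsilon  # 3 + 3 * 1.4826
#' @export
dbscanEpsilon <- function(nnds, minSamples = 3L) {
    if (!length(nnds)) stop("dbscanEpsilon: empty NND set")
    list(epsilon = stats::median(nnds) + 3 * scaledMad(nnds),
         minSamples = as.integer(minSamples),
         c = madScaleConstant())
}

#' Density-based clustering (DBSCAN) of cluster centroids
#'
#' Classic DBSCAN on a 3D point set: points with at least \code{minPts}
#' neighbors within \code{eps} (themselves included) are core points;
#' non-core points within \code{eps} of a core point are border points;
#' everything else is noise. Clusters are the connected components of core
#' points (linked when within \code{eps}), with border points attached to
#' the cluster of the first core point that reaches them.
#'
#' @param points numeric matrix (n x 3).
#' @param eps neighborhood radius (same units as the coordinates).
#' @param minPts core-point threshold (neighbors within eps, self included).
#' @return list with \code{cluster} (integer labels, 0 = noise) and
#'   \code{type} (character: "core", "border", "noise").
#' @export
runDBSCAN <- function(points, eps, minPts = 3L) {
    points <- .asPointMatrix(points)
    n <- nrow(points)
    if (n < minPts) stop("fewer points than minPts")
    eps2 <- eps^2
    # neighbor lists (self included), blocked
    nbrs <- vector("list", n)
    chunk <- 1024L
    for (start in seq.int(1L, n, by = chunk)) {
        idx <- start:min(start + chunk - 1L, n)
        d2 <- .crossDist2(points[idx, , drop = FALSE], points)
        for (k in seq_along(idx)) nbrs[[idx[k]]] <- which(d2[k, ] <= eps2)
    }
    core <- lengths(nbrs) >= minPts
    labels <- integer(n)
    type <- rep("noise", n)
    type[core] <- "core"
    cl <- 0L
    for (i in which(core)) {
        if (labels[i] != 0L) next
        cl <- cl + 1L
        labels[i] <- cl
        queue <- i
        while (length(queue)) {
            j <- queue[[1]]
            queue <- queue[-1]
            for (k in nbrs[[j]]) {
                if (core[k]) {
                    if (labels[k] == 0L) {
                        labels[k] <- cl
                        queue <- c(queue, k)
                    }
                } else if (labels[k] == 0L) {
                    labels[k] <- cl
                    type[k] <- "border"
                }
            }
        }
    }
    list(cluster = labels, type = type)
}

#' Extract the cell from a cluster table by density clustering
#'
#' Runs DBSCAN on the cluster centroids and flags membership in the largest
#' density cluster, which is the cell itself; low-density stray clusters
#' (false positives of the upstream segmentation) are left unflagged. When
#' \code{params} is NULL, epsilon is derived from the nearest-neighbor
#' distances of all centroids via [dbscanEpsilon()].
#'
#' @param cs a [ClusterSet-class].
#' @param params optional list with \code{epsilon} and \code{minSamples}
#'   (as returned by [dbscanEpsilon()]).
#' @return the ClusterSet with the \code{in_cell} flag set.
#' @export
extractCell <- function(cs, params = NULL) {
    stopifnot(is(cs, "ClusterSet"))
    pts <- centroids(cs)
    if (is.null(params))
        params <- dbscanEpsilon(nearestNeighborDistances(pts))
    db <- runDBSCAN(pts, eps = params$epsilon, minPts = params$minSamples)
    if (all(db$cluster == 0L))
        stop("no cell found: all clusters classified as noise")
    largest <- which.max(tabulate(db$cluster))
    df <- cs@clusters
    df$in_cell <- db$cluster == largest
    initialize(cs, clusters = df,
               metadata = c(cs@metadata,
                            list(dbscan = c(params, list(
                                nClusters = max(db$cluster),
                                nNoise = sum(db$cluster == 0L))))))
}

#' Tukey's fences outlier filter
#'
#' Keeps values inside the closed interval
#' \eqn{[Q_1 - k (Q_3 - Q_1),\ Q_3 + k (Q_3 - Q_1)]} with fence multiplier
#' \eqn{k = 3} (far outliers). Quartiles use linear interpolation between
#' order statistics (quantile type 7).
#'
#' @param values numeric vector.
#' @param k fence multiplier (default 3.0).
#' @return list with \code{values} (kept values) and \code{mask} (logical,
#'   TRUE for kept entries, same length as the input).
#' @examples
#' tukeyFilter(c(1:10, 100))$mask  # the 100 is fenced out
#' @export
tukeyFilter <- function(values, k = 3.0) {
    n <- length(values)
    if (n < 4) {
        warning("tukeyFilter: fewer than 4 values, no filtering applied")
        return(list(values = values, mask = rep(TRUE, n)))
    }
    q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    mask <- values >= q[1] - k * iqr & values <= q[2] + k * iqr
    list(values = values[mask], mask = mask)
}
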