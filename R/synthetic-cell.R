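# Synthetic SANC-like cluster datasets with planted ground truth, so every
# analysis stage can be exercised end-to-end without imaging data.

#' Specification of a synthetic cell
#'
#' Describes a surface-constrained cluster pattern emulating the measured
#' regime: clusters on an ellipsoidal cell surface with a hard-core
#' (repulsive), Poisson, or jittered-lattice layout, volumes drawn from a
#' two-component Gamma mixture, plus planted far-off-surface noise points
#' (to exercise DBSCAN noise removal) and extreme size outliers (to
#' exercise Tukey's fences).
#'
#' The defaults mimic the average measured cell: ~2285 clusters on an
#' ellipsoid of surface area ~2500 um^2, sizes from the aggregated
#' two-component mixture (shapes 4.35/2.22, rates 125/10.64, weight 0.16),
#' and a hard-core radius that brings the mean NND near the measured
#' 639 nm.
#'
#' @param semiAxes ellipsoid semi-axes in um.
#' @param nClusters number of surface clusters.
#' @param pointProcess "hardcore", "poisson", or "lattice".
#' @param hardcoreRadius hard-core (Matern II) radius in nm.
#' @param sizeModel Gamma mixture parameters: list(shape, rate, weight).
#' @param nNoisePoints planted far-off-surface noise points.
#' @param nExtremeOutliers planted extreme-volume outliers (on-surface).
#' @param seed integer seed; recorded in every generated object.
#' @return list of class \code{"SyntheticCellSpec"}.
#' @export
syntheticCellSpec <- function(semiAxes = c(35, 7.1, 7.1),
                              nClusters = 2285L,
                              pointProcess = c("hardcore", "poisson",
                                               "lattice"),
                              hardcoreRadius = 390,
                              sizeModel = list(shape = c(4.35, 2.22),
                                               rate = c(125, 10.64),
                                               weight = c(0.16, 0.84)),
                              nNoisePoints = 20L,
                              nExtremeOutliers = 5L,
                              seed = 1L) {
    pointProcess <- match.arg(pointProcess)
    stopifnot(length(semiAxes) == 3, all(semiAxes > 0), nClusters >= 4,
              nNoisePoints >= 0, nExtremeOutliers >= 0)
    if (pointProcess == "hardcore") stopifnot(hardcoreRadius > 0)
    spec <- list(semiAxes = as.numeric(semiAxes),
                 nClusters = as.integer(nClusters),
                 pointProcess = pointProcess,
                 hardcoreRadius = hardcoreRadius,
                 sizeModel = sizeModel,
                 nNoisePoints = as.integer(nNoisePoints),
                 nExtremeOutliers = as.integer(nExtremeOutliers),
                 seed = as.integer(seed))
    class(spec) <- "SyntheticCellSpec"
    spec
}

#' @export
print.SyntheticCellSpec <- function(x, ...) {
    cat("SyntheticCellSpec:", x$nClusters, "clusters,", x$pointProcess,
        "process on ellipsoid", paste(x$semiAxes, collapse = " x "),
        "um\n")
    cat("  noise points:", x$nNoisePoints, " extreme outliers:",
        x$nExtremeOutliers, " seed:", x$seed, "\n")
    invisible(x)
}

# Area-uniform points on an ellipsoid surface (nm), by mapping uniform
# sphere directions and rejecting with the surface-element weight.
.ellipsoidSurfacePoints <- function(n, semiAxes) {
    a <- semiAxes[1]; b <- semiAxes[2]; c_ <- semiAxes[3]
    wmax <- max(a * b, a * c_, b * c_)
    out <- matrix(numeric(0), 0, 3)
    while (nrow(out) < n) {
        m <- max(2L * (n - nrow(out)), 256L)
        u <- matrix(stats::rnorm(3 * m), m, 3)
        u <- u / sqrt(rowSums(u^2))
        w <- sqrt((u[, 1] * b * c_)^2 + (u[, 2] * a * c_)^2 +
                  (u[, 3] * a * b)^2)
        keep <- stats::runif(m) < w / wmax
        if (any(keep))
            out <- rbind(out, sweep(u[keep, , drop = FALSE], 2, semiAxes,
                                    "*"))
    }
    out[seq_len(n), , drop = FALSE] * 1000  # um -> nm
}

# Approximate ellipsoid surface area (Thomsen's formula, ~1% accurate).
.ellipsoidArea <- function(semiAxes) {
    p <- 1.6075
    a <- semiAxes[1]^p; b <- semiAxes[2]^p; c_ <- semiAxes[3]^p
    4 * pi * ((a * b + a * c_ + b * c_) / 3)^(1 / p)
}

#' Sample cluster centroids on an ellipsoid surface
#'
#' \code{"poisson"}: area-uniform points. \code{"hardcore"}: Matern type-II
#' thinning of an area-uniform proposal at the given radius (no kept point
#' has an earlier-marked proposal within the radius), then subsampled to n;
#' the minimum pairwise distance is at least the radius. \code{"lattice"}:
#' a jittered quasi-regular (Fibonacci) surface grid. Deterministic per
#' seed.
#'
#' @param n number of points.
#' @param semiAxes ellipsoid semi-axes in um.
#' @param process "poisson", "hardcore" or "lattice".
#' @param hardcoreRadius Matern II radius in nm.
#' @param seed integer seed.
#' @param jitterSd lattice jitter, as a fraction of the grid spacing.
#' @return numeric matrix (n x 3) of coordinates in nm.
#' @export
sampleSurfacePoints <- function(n, semiAxes = c(35, 7.1, 7.1),
                                process = c("poisson", "hardcore",
                                            "lattice"),
                                hardcoreRadius = 390, seed = 1L,
                                jitterSd = 0.15) {
    process <- match.arg(process)
    .withSeed(seed, {
        if (process == "poisson") {
            .ellipsoidSurfacePoints(n, semiAxes)
        } else if (process == "hardcore") {
            area_nm2 <- .ellipsoidArea(semiAxes) * 1e6  # um^2 -> nm^2
            r <- hardcoreRadius
            # Matern II retention on a surface: lambda_kept =
            # (1 - exp(-lambda_p pi r^2)) / (pi r^2); invert for lambda_p
            discArea <- pi * r^2
            targetLambda <- n / area_nm2
            maxLambda <- 0.98 / discArea
            if (targetLambda > maxLambda)
                stop(sprintf(paste0(
                    "hard-core radius too large: at radius %.0f nm at ",
                    "most ~%d points fit on this surface"),
                    r, floor(maxLambda * area_nm2)))
            lambdaP <- -log(1 - targetLambda * discArea) / discArea
            m <- ceiling(1.25 * lambdaP * area_nm2)
            cand <- .ellipsoidSurfacePoints(m, semiAxes)
            marks <- stats::runif(m)
            keep <- rep(TRUE, m)
            chunk <- 1024L
            for (start in seq.int(1L, m, by = chunk)) {
                idx <- start:min(start + chunk - 1L, m)
                d2 <- .crossDist2(cand[idx, , drop = FALSE], cand)
                d2[cbind(seq_along(idx), idx)] <- Inf
                within <- d2 < r^2
                for (k in seq_along(idx))
                    keep[idx[k]] <- !any(within[k, ] &
                                         marks < marks[idx[k]])
            }
            kept <- which(keep)
            if (length(kept) < n)
                stop(sprintf(paste0(
                    "hard-core radius too large: only %d of %d points ",
                    "achievable at radius %.0f nm"),
                    length(kept), n, hardcoreRadius))
            cand[sample(kept, n), , drop = FALSE]
        } else {
            # Fibonacci sphere grid mapped to the ellipsoid, with jitter
            i <- seq_len(n) - 0.5
            phi <- acos(1 - 2 * i / n)
            theta <- pi * (1 + sqrt(5)) * i
            u <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta),
                       cos(phi))
            spacing <- sqrt(4 * pi / n)  # angular grid spacing
            u <- u + matrix(stats::rnorm(3 * n, 0, jitterSd * spacing),
                            n, 3)
            u <- u / sqrt(rowSums(u^2))
            sweep(u, 2, semiAxes, "*") * 1000
        }
    })
}

#' Draw cluster volumes from the Gamma mixture ground truth
#'
#' Draws volumes (um^3) from the two-component Gamma mixture and records
#' the generating component of every draw as the \code{"component"}
#' attribute -- the planted ground truth for classification checks.
#'
#' @param n number of draws.
#' @param sizeModel mixture parameters (list(shape, rate, weight)) or a
#'   [GammaMixtureFit-class]; defaults to the aggregated parameters.
#' @param seed integer seed.
#' @return numeric vector with attribute \code{component}.
#' @export
sampleSizes <- function(n, sizeModel = list(shape = c(4.35, 2.22),
                                            rate = c(125, 10.64),
                                            weight = c(0.16, 0.84)),
                        seed = 1L) {
    rGammaMixture(n, sizeModel, seed = seed)
}

#' Build a synthetic cell with planted ground truth
#'
#' Combines surface clusters, far-off-surface noise points (placed well
#' beyond 5x the expected mean NND, mutually separated so that DBSCAN must
#' classify them as noise), and extreme-volume outliers (well beyond the
#' upper Tukey fence of the size distribution). Every planted label is
#' returned as ground truth, and the full spec and seed are embedded in
#' the output's metadata, making the fixture self-describing.
#'
#' @param spec a [syntheticCellSpec()].
#' @return list with \code{clusterSet} (a [ClusterSet-class]) and
#'   \code{truth} (data.frame: id, role ("cell", "noise",
#'   "size_outlier"), sizeComponent).
#' @examples
#' cell <- makeSyntheticCell(syntheticCellSpec(nClusters = 300,
#'                                             nNoisePoints = 5, seed = 2))
#' table(cell$truth$role)
#' @export
makeSyntheticCell <- function(spec) {
    stopifnot(inherits(spec, "SyntheticCellSpec"))
    n <- spec$nClusters
    surface <- sampleSurfacePoints(n, spec$semiAxes, spec$pointProcess,
                                   spec$hardcoreRadius, seed = spec$seed)
    vols <- sampleSizes(n, spec$sizeModel, seed = spec$seed + 1L)
    comp <- attr(vols, "component")
    role <- rep("cell", n)

    .withSeed(spec$seed + 2L, {
        if (spec$nExtremeOutliers > 0) {
            out <- sample.int(n, spec$nExtremeOutliers)
            # far beyond the upper Tukey fence of the mixture (~0.7 um^3)
            vols[out] <- stats::runif(spec$nExtremeOutliers, 3, 5)
            role[out] <- "size_outlier"
        }
        if (spec$nNoisePoints > 0) {
            # isolated points far outside the surface: offset along the
            # outward radial direction by >= 5 um (~8x the mean NND), with
            # >= 4 um mutual separation so no dense pocket can form
            noise <- matrix(NA_real_, spec$nNoisePoints, 3)
            placed <- 0L
            while (placed < spec$nNoisePoints) {
                u <- stats::rnorm(3)
                u <- u / sqrt(sum(u^2))
                pt <- (spec$semiAxes * u +
                       u * stats::runif(1, 5, 15)) * 1000
                if (placed == 0L ||
                    min(.crossDist2(matrix(pt, 1),
                                    noise[seq_len(placed), , drop = FALSE])) >
                        (4000)^2) {
                    placed <- placed + 1L
                    noise[placed, ] <- pt
                }
            }
            surface <- rbind(surface, noise)
            nv <- sampleSizes(spec$nNoisePoints, spec$sizeModel,
                              seed = spec$seed + 3L)
            comp <- c(comp, attr(nv, "component"))
            vols <- c(vols, as.numeric(nv))
            role <- c(role, rep("noise", spec$nNoisePoints))
        }
    })

    ntot <- nrow(surface)
    df <- data.frame(id = seq_len(ntot), x = surface[, 1],
                     y = surface[, 2], z = surface[, 3],
                     volume = as.numeric(vols))
    cs <- ClusterSet(df, metadata = list(synthetic = TRUE,
                                         spec = unclass(spec),
                                         seed = spec$seed))
    truth <- data.frame(id = seq_len(ntot), role = role,
                        sizeComponent = comp)
    list(clusterSet = cs, truth = truth)
}
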