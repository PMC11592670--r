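# CRU network generation: positions along a repulsion schedule from uniform
# random (step 0) towards a crystal-like arrangement (step 100), plus RyR
# count assignment under exact total-RyR conservation.

#' Rectangular CRU domain
#'
#' A (periodic) rectangular sheet abstracting the submembrane CRU layer.
#' When width/height are omitted they are chosen as a square whose area
#' matches the average experimental cluster density (2285 clusters on
#' 2505 um^2 of cell surface).
#'
#' @param n number of CRUs (used to size the default domain).
#' @param width,height domain size in nm.
#' @param periodic logical; periodic boundaries (default TRUE).
#' @param density clusters per um^2 used for the default sizing.
#' @return list(width, height, periodic) in nm.
#' @export
cruDomain <- function(n = NULL, width = NULL, height = NULL, periodic = TRUE,
                      density = 2285 / 2505) {
    if (is.null(width) || is.null(height)) {
        if (is.null(n)) stop("either n or width/height must be given")
        side <- sqrt(n / density) * 1000  # nm
        width <- height <- side
    }
    stopifnot(width > 0, height > 0)
    list(width = width, height = height, periodic = isTRUE(periodic))
}

# NND in the domain metric (minimum-image for periodic domains).
.nndDomain <- function(p, domain) {
    .nndDomain_cpp(p, domain$width, domain$height,
                   isTRUE(domain$periodic))
}

# One repulsion iteration: points closer than the interaction radius push
# each other apart along their separation vector; displacements are capped
# and positions wrapped back into the domain. Returns the updated positions
# plus the mean NND of the *input* configuration (a free byproduct of the
# pair scan, used by the trajectory trace).
.repelOnce <- function(p, domain, rInt, gain, maxDisp) {
    .repelStep_cpp(p, domain$width, domain$height,
                   isTRUE(domain$periodic), rInt, gain, maxDisp)
}

# Shared engine: runs the schedule up to `step`, optionally recording the
# mean NND after every iteration (including step 0).
.runSchedule <- function(n, domain, step, seed, nSteps = 100L,
                         rIntFactor = 1.5, gain = 0.15, dispCap = 0.1,
                         trace = FALSE) {
    stopifnot(n >= 2, step >= 0, step <= nSteps)
    area <- domain$width * domain$height
    aCryst <- sqrt(2 * area / (n * sqrt(3)))  # hexagonal lattice spacing
    rInt <- rIntFactor * aCryst
    p <- .withSeed(seed, cbind(stats::runif(n, 0, domain$width),
                               stats::runif(n, 0, domain$height)))
    meanNnd <- if (trace) numeric(step + 1L) else NULL
    for (t in seq_len(step)) {
        g <- gain * t / nSteps  # annealed upward: none -> strongest
        res <- .repelOnce(p, domain, rInt, g, maxDisp = dispCap * aCryst)
        if (trace) meanNnd[t] <- res$nndIn
        p <- res$p
    }
    if (trace) meanNnd[step + 1L] <- mean(.nndDomain(p, domain))
    list(positions = p, meanNnd = meanNnd, aCryst = aCryst, rInt = rInt)
}

#' Generate CRU positions along the repulsion schedule
#'
#' Positions start uniformly random (step 0) and are evolved by a pairwise
#' short-range repulsion rule: at every iteration, each pair of CRUs closer
#' than the interaction radius (1.5 x the crystal lattice spacing for the
#' given density) is pushed apart along its separation vector, with a gain
#' annealed upward over the schedule and displacements capped at a tenth of
#' the lattice spacing. By step 100 the arrangement approaches a near-hexagonal,
#' crystal-like packing. The evolution is deterministic given the seed.
#'
#' @param n number of CRUs (>= 2).
#' @param domain a [cruDomain()]; defaults to the density-matched square.
#' @param step repulsion step in 0..100.
#' @param seed integer seed for the initial uniform positions.
#' @param rIntFactor interaction radius in units of the crystal spacing.
#' @param gain repulsion gain reached at the final step.
#' @return numeric matrix (n x 2) of positions in nm.
#' @export
generatePositions <- function(n, domain = NULL, step = 0L, seed = 1L,
                              rIntFactor = 1.5, gain = 0.15) {
    if (is.null(domain)) domain <- cruDomain(n)
    .runSchedule(n, domain, as.integer(step), seed,
                 rIntFactor = rIntFactor, gain = gain)$positions
}

#' Mean-NND trajectory of the repulsion schedule
#'
#' Runs the full repulsion schedule once and records the mean
#' nearest-neighbor distance at every step (0..nSteps). Used by
#' [calibrateStep()] and by the schedule's monotonicity diagnostics.
#'
#' @inheritParams generatePositions
#' @param nSteps schedule length (default 100).
#' @return numeric vector of length nSteps + 1 (mean NND at steps 0..nSteps).
#' @export
repulsionTrajectory <- function(n, domain = NULL, seed = 1L, nSteps = 100L,
                                rIntFactor = 1.5, gain = 0.15) {
    if (is.null(domain)) domain <- cruDomain(n)
    .runSchedule(n, domain, nSteps, seed, nSteps = nSteps,
                 rIntFactor = rIntFactor, gain = gain, trace = TRUE)$meanNnd
}

#' Calibrate the repulsion step to a target mean NND
#'
#' Finds the repulsion step whose ensemble mean NND (averaged over seeds)
#' is closest to the target -- e.g. the experimentally measured mean
#' nearest-neighbor distance -- exploiting that the mean NND grows
#' monotonically along the schedule. The realistic network sits at an
#' intermediate step between the uniform-random and crystal-like extremes.
#'
#' @param targetMeanNnd target mean NND in nm.
#' @param n number of CRUs.
#' @param domain a [cruDomain()] (default density-matched square).
#' @param seeds integer vector of seeds to average over.
#' @param ... passed to [repulsionTrajectory()].
#' @return the calibrated step index (0..100); the achieved ensemble mean
#'   NND is attached as attribute \code{"meanNnd"}, the full ensemble
#'   trajectory as \code{"trajectory"}.
#' @export
calibrateStep <- function(targetMeanNnd, n, domain = NULL, seeds = 1:3,
                          ...) {
    if (is.null(domain)) domain <- cruDomain(n)
    traj <- rowMeans(vapply(seeds, function(s)
        repulsionTrajectory(n, domain, seed = s, ...),
        numeric(101L)))
    lo <- traj[1]
    hi <- max(traj)
    if (targetMeanNnd < lo || targetMeanNnd > hi)
        stop(sprintf(
            "target mean NND %.1f nm outside achievable range [%.1f, %.1f]",
            targetMeanNnd, lo, hi))
    step <- which.min(abs(traj - targetMeanNnd)) - 1L
    structure(step, meanNnd = traj[step + 1L], trajectory = traj)
}

#' Map a cluster volume to an RyR count
#'
#' Linear calibration: \code{count = round(k * volume)} with k chosen so
#' the mean volume of the size distribution maps to the average CRU size of
#' 48 RyRs; counts are clamped to at least 1.
#'
#' @param volume cluster volume(s), um^3.
#' @param meanVolume mean volume of the reference size distribution, um^3.
#' @param meanCount RyR count assigned to the mean volume (default 48).
#' @return integer RyR count(s).
#' @export
volumeToRyr <- function(volume, meanVolume, meanCount = 48) {
    stopifnot(all(volume > 0), meanVolume > 0)
    pmax(1L, as.integer(round(meanCount * volume / meanVolume)))
}

#' Assign per-CRU RyR counts under exact total conservation
#'
#' \code{"identical"} gives every CRU 48 RyRs (the average CRU size of the
#' realistic distribution) and requires \code{totalRyr = 48 n}.
#' \code{"realistic"} draws volumes from a fitted Gamma mixture (or
#' resamples an empirical volume set), maps them linearly to RyR counts,
#' and applies largest-remainder rounding so the counts sum exactly to
#' \code{totalRyr}; every CRU keeps at least 1 RyR.
#'
#' @param n number of CRUs.
#' @param mode \code{"identical"} or \code{"realistic"}.
#' @param totalRyr total RyR budget (default 48 n, so that all generated
#'   cell models share the same total number of RyRs).
#' @param sizeDistribution for realistic mode: a
#'   [GammaMixtureFit-class], a parameter list accepted by
#'   [rGammaMixture()], or a numeric vector of empirical volumes.
#' @param seed seed for the volume draws.
#' @return integer vector of RyR counts summing exactly to totalRyr.
#' @export
assignSizes <- function(n, mode = c("identical", "realistic"),
                        totalRyr = 48L * n, sizeDistribution = NULL,
                        seed = NULL) {
    mode <- match.arg(mode)
    n <- as.integer(n)
    totalRyr <- as.integer(totalRyr)
    if (totalRyr < n)
        stop("infeasible total: need at least 1 RyR per CRU")
    if (mode == "identical") {
        if (totalRyr != 48L * n)
            stop("identical mode requires totalRyr = 48 * n")
        return(rep.int(48L, n))
    }
    if (is.null(sizeDistribution))
        stop("realistic mode needs a size distribution")
    if (is.numeric(sizeDistribution)) {
        vols <- .withSeed(seed,
            sample(sizeDistribution, n, replace = TRUE))
    } else {
        vols <- as.numeric(rGammaMixture(n, sizeDistribution, seed = seed))
    }
    raw <- vols * totalRyr / sum(vols)   # exact-conservation scaling
    base <- floor(raw)
    rem <- totalRyr - sum(base)
    frac <- raw - base
    add <- integer(n)
    if (rem > 0)
        add[order(frac, decreasing = TRUE)[seq_len(rem)]] <- 1L
    counts <- as.integer(base + add)
    # enforce the minimum of 1 RyR, taking the excess from the largest CRUs
    deficit <- sum(pmax(1L - counts, 0L))
    counts <- pmax(counts, 1L)
    while (deficit > 0) {
        big <- which.max(counts)
        take <- min(deficit, counts[big] - 1L)
        counts[big] <- counts[big] - take
        deficit <- deficit - take
        if (take == 0L) stop("infeasible total")
    }
    counts
}

#' Generate a complete CRU network
#'
#' Convenience wrapper combining [generatePositions()] and [assignSizes()]
#' into a [CRUNetwork-class] ready to hand to a pacemaker-cell simulator.
#'
#' @inheritParams generatePositions
#' @inheritParams assignSizes
#' @examples
#' net <- generateNetwork(200, step = 0, seed = 7)
#' totalRyr(net)  # 9600
#' @return a [CRUNetwork-class].
#' @export
generateNetwork <- function(n, domain = NULL, step = 0L, seed = 1L,
                            mode = c("identical", "realistic"),
                            totalRyr = 48L * n, sizeDistribution = NULL,
                            rIntFactor = 1.5, gain = 0.15) {
    mode <- match.arg(mode)
    if (is.null(domain)) domain <- cruDomain(n)
    pos <- generatePositions(n, domain, step = step, seed = seed,
                             rIntFactor = rIntFactor, gain = gain)
    counts <- assignSizes(n, mode = mode, totalRyr = totalRyr,
                          sizeDistribution = sizeDistribution,
                          seed = if (is.null(seed)) NULL else seed + 1L)
    new("CRUNetwork", positions = pos, ryrCounts = counts,
        step = as.integer(step), domain = domain,
        totalRyr = as.integer(totalRyr),
        meanNnd = mean(.nndDomain(pos, domain)),
        seed = as.integer(seed),
        metadata = list(mode = mode, rIntFactor = rIntFactor, gain = gain))
}

#' Nearest-neighbor distances of a CRU network
#'
#' NND of the network positions in the domain metric (minimum-image
#' distances for periodic domains).
#'
#' @param net a [CRUNetwork-class].
#' @return numeric vector of distances in nm.
#' @export
networkNnd <- function(net) {
    .nndDomain(positions(net), networkDomain(net))
}
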