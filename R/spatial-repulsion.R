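#' Histogram of nearest-neighbor distances
#'
#' Equal-width histogram over \[min, max\] of the distances, the raw
#' material of the power-law repulsion analysis. 50 bins are used for
#' per-cell analyses.
#'
#' @param nnds numeric vector of nearest-neighbor distances (nm), n >= 2.
#' @param nBins number of bins (default 50).
#' @return list of class \code{"NNDHistogram"}: \code{edges},
#'   \code{counts}, \code{centers}, \code{peakIndex} (first maximum),
#'   \code{n}.
#' @export
nndHistogram <- function(nnds, nBins = 50L) {
    nnds <- as.numeric(nnds)
    if (length(nnds) < 2) stop("need at least 2 distances")
    if (anyNA(nnds) || any(!is.finite(nnds)))
        stop("distances must be finite")
    rng <- range(nnds)
    if (rng[1] == rng[2]) {
        warning("all distances equal: degenerate single-bin histogram")
        h <- list(edges = c(rng[1] - 0.5, rng[1] + 0.5),
                  counts = length(nnds), centers = rng[1],
                  peakIndex = 1L, n = length(nnds))
        class(h) <- "NNDHistogram"
        return(h)
    }
    edges <- seq(rng[1], rng[2], length.out = nBins + 1)
    counts <- graphics::hist(nnds, breaks = edges, plot = FALSE)$counts
    h <- list(edges = edges, counts = counts,
              centers = (edges[-1] + edges[-length(edges)]) / 2,
              peakIndex = which.max(counts), n = length(nnds))
    class(h) <- "NNDHistogram"
    h
}

#' @export
print.NNDHistogram <- function(x, ...) {
    cat("NNDHistogram:", length(x$counts), "bins over [",
        signif(x$edges[1], 5), ",", signif(x$edges[length(x$edges)], 5),
        "] nm, n =", x$n, "\n")
    cat("  peak at bin", x$peakIndex, "(count", x$counts[x$peakIndex],
        ")\n")
    invisible(x)
}

#' Ascending bin range of an NND histogram
#'
#' The bins used for the power-law fit: the ascending left tail of the
#' histogram, from the first nonzero bin up to (and excluding) the first
#' bin whose count reaches half of the peak count. Zero-count bins inside
#' the range are excluded (their log is undefined). The alternative rule
#' \code{"to_peak"} extends the range to just below the peak bin instead.
#'
#' @param hist an \code{"NNDHistogram"} from [nndHistogram()].
#' @param rule stopping rule: \code{"below_half_peak"} (default) or
#'   \code{"to_peak"}.
#' @return integer vector of bin indices with positive counts.
#' @examples
#' h <- structure(list(counts = c(1, 2, 4, 8, 16, 20, 18),
#'                     centers = 1:7, peakIndex = 6L),
#'                class = "NNDHistogram")
#' ascendingRange(h)  # bins 1:4 (counts 1, 2, 4, 8)
#' @export
ascendingRange <- function(hist, rule = c("below_half_peak", "to_peak")) {
    rule <- match.arg(rule)
    counts <- hist$counts
    peak <- hist$peakIndex
    half <- counts[peak] / 2
    stopAt <- switch(rule,
        below_half_peak = {
            i <- which(counts >= half)[1]  # always exists (the peak)
            i
        },
        to_peak = peak)
    firstNonzero <- which(counts > 0)[1]
    if (is.na(firstNonzero) || stopAt <= firstNonzero)
        stop("ascending range is empty; increase the number of bins")
    idx <- firstNonzero:(stopAt - 1L)
    idx <- idx[counts[idx] > 0]
    if (!length(idx))
        stop("ascending range is empty; increase the number of bins")
    as.integer(idx)
}

#' Power-law fit to the ascending NND histogram
#'
#' Fits \eqn{p(x) = A x^b} by ordinary least squares of
#' \eqn{\log p(x) = \log A + b \log x} at the bin centers of the ascending
#' range, on the density scale (counts / (n * bin width)). The exponent
#' classifies the point pattern: \eqn{b \approx 1} a random Poisson
#' process, \eqn{b > 1} repulsion between clusters, \eqn{b < 1}
#' clustering; the implementation uses bands at \eqn{1 \pm 0.2}.
#'
#' @param hist an \code{"NNDHistogram"}.
#' @param range bin indices to fit; defaults to [ascendingRange()].
#' @param bands numeric(2), the classification band around 1
#'   (default c(0.8, 1.2)).
#' @param rule stopping rule passed to [ascendingRange()] when
#'   \code{range} is NULL.
#' @return a [PowerLawFit-class].
#' @export
fitPowerLaw <- function(hist, range = NULL, bands = c(0.8, 1.2),
                        rule = "below_half_peak") {
    if (is.null(range)) range <- ascendingRange(hist, rule = rule)
    range <- range[hist$counts[range] > 0]
    if (length(range) < 2)
        stop("need at least 2 bins with positive counts to fit")
    width <- diff(hist$edges[1:2])
    dens <- hist$counts[range] / (hist$n * width)
    lx <- log(hist$centers[range])
    ly <- log(dens)
    fit <- stats::lm.fit(cbind(1, lx), ly)
    b <- unname(fit$coefficients[2])
    r2 <- if (stats::var(ly) > 0) 1 - sum(fit$residuals^2) /
        sum((ly - mean(ly))^2) else 1
    cls <- if (b < bands[1]) "clustering"
           else if (b <= bands[2]) "poisson" else "repulsion"
    new("PowerLawFit", exponent = b,
        logIntercept = unname(fit$coefficients[1]),
        rSquared = r2, fitBins = as.integer(range),
        classification = cls, histogram = unclass(hist))
}
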